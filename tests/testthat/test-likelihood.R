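test_that("pruning matches the exhaustive oracle on small GTR problems", {
  set.seed(44)
  rates <- c(1.3, 4.2, 0.7, 1.1, 5.5, 1)
  freqs <- c(0.31, 0.24, 0.17, 0.28)
  model <- substitution_model(rates = rates, base_freqs = freqs)
  for (i in 1:3) {
    tree <- ape::rtree(4)
    tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.6)
    aln <- random_alignment(4, 30, seed = i)
    rownames(aln$seq) <- tree$tip.label
    aln <- dna_alignment(aln$seq)
    expect_equal(tree_log_likelihood(aln, tree, model),
                 oracle_loglik(aln, tree, rates, freqs),
                 tolerance = 1e-8)
  }
})

test_that("two-taxon JC likelihood matches the closed form", {
  model <- substitution_model()
  t <- 0.37
  p_same <- 0.25 + 0.75 * exp(-4 * t / 3)
  p_diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  tree <- ape::read.tree(text = "(x:0.17,y:0.2);")
  same <- aln_from_columns(list("AA"), taxa = c("x", "y"))
  diff <- aln_from_columns(list("AC"), taxa = c("x", "y"))
  expect_equal(tree_log_likelihood(same, tree, model),
               log(0.25 * p_same), tolerance = 1e-10)
  expect_equal(tree_log_likelihood(diff, tree, model),
               log(0.25 * p_diff), tolerance = 1e-10)
})

test_that("likelihood is invariant to re-rooting and matches phangorn with +G+I", {
  set.seed(55)
  tree <- ape::rtree(8)
  tree$edge.length <- runif(nrow(tree$edge), 0.02, 0.5)
  cfg <- test_config(n_taxa = 8, lengths = 400, seed = 5)
  aln <- evolve_alignment(tree, cfg)
  model <- substitution_model(rates = c(1.2, 3.5, 0.8, 1.1, 4.4, 1),
                              base_freqs = c(0.3, 0.22, 0.21, 0.27),
                              p_invariant = 0.2, gamma_shape = 0.7)
  ll <- tree_log_likelihood(aln, tree, model)

  rerooted <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[5],
                        resolve.root = TRUE)
  expect_equal(tree_log_likelihood(aln, rerooted, model), ll, tolerance = 1e-8)

  dat <- phangorn::phyDat(aln$seq)
  fit <- phangorn::pml(tree, dat, bf = model$base_freqs, Q = model$rates,
                       inv = 0.2, shape = 0.7, k = 4)
  expect_equal(ll, as.numeric(fit$logLik), tolerance = 1e-6)

  # site log-likelihoods sum to the total
  expect_equal(sum(site_log_likelihoods(aln, tree, model)), ll,
               tolerance = 1e-10)
})

test_that("ambiguity codes integrate over compatible states", {
  model <- substitution_model()
  tree <- ape::read.tree(text = "(x:0.1,y:0.1);")
  # N on one side: likelihood equals sum over 4 resolutions = marginal of x
  amb <- aln_from_columns(list("AN"), taxa = c("x", "y"))
  expect_equal(tree_log_likelihood(amb, tree, model), log(0.25),
               tolerance = 1e-10)
  # R = A or G: sum of the two resolved likelihoods
  r <- aln_from_columns(list("AR"), taxa = c("x", "y"))
  la <- exp(tree_log_likelihood(aln_from_columns(list("AA"), taxa = c("x", "y")),
                                tree, model))
  lg <- exp(tree_log_likelihood(aln_from_columns(list("AG"), taxa = c("x", "y")),
                                tree, model))
  expect_equal(exp(tree_log_likelihood(r, tree, model)), la + lg,
               tolerance = 1e-12)
})

test_that("discrete gamma rate classes have mean one and are ordered", {
  for (alpha in c(0.2, 0.5, 1, 3)) {
    r <- discrete_gamma_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(discrete_gamma_rates(0.5, 1), 1, tolerance = 1e-9)
  # smaller alpha means more rate heterogeneity (wider spread)
  expect_gt(diff(range(discrete_gamma_rates(0.2, 4))),
            diff(range(discrete_gamma_rates(2, 4))))
})

test_that("branch-length optimization improves and recovers generating lengths", {
  cfg <- test_config(n_taxa = 6, lengths = 5000, seed = 8)
  tree <- simulate_tree(cfg)
  aln <- evolve_alignment(tree, cfg)
  model <- cfg$model

  start <- tree
  start$edge.length <- rep(0.1, nrow(tree$edge))
  fit <- optimize_branch_lengths(aln, start, model)
  ll0 <- tree_log_likelihood(aln, start, model)
  ll1 <- attr(fit, "loglik")
  expect_gt(ll1, ll0)
  expect_equal(tree_log_likelihood(aln, fit, model), ll1, tolerance = 1e-9)

  # refitting from the optimum changes the likelihood only marginally
  refit <- optimize_branch_lengths(aln, fit, model)
  expect_lt(abs(attr(refit, "loglik") - ll1), 0.1)

  # total tree length recovered within 10%
  expect_equal(sum(fit$edge.length), sum(tree$edge.length), tolerance = 0.1)
})

test_that("SH test gives the best tree p = 1 and is deterministic", {
  cfg <- test_config(n_taxa = 8, lengths = 800, seed = 12)
  tree <- simulate_tree(cfg)
  aln <- evolve_alignment(tree, cfg)
  model <- cfg$model
  trees <- list(true = tree, alt = nni_neighbor(tree, edge = 2))

  res <- sh_test(aln, trees, model, n_replicates = 200, seed = 31)
  expect_s3_class(res, "sh_test_result")
  best <- res$tree_id[which.max(res$log_likelihood)]
  expect_equal(res$p_value[res$tree_id == best], 1)
  expect_equal(res$delta[res$tree_id == best], 0)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  res2 <- sh_test(aln, trees, model, n_replicates = 200, seed = 31)
  expect_identical(res, res2)

  # duplicate topologies cannot be rejected against each other
  res3 <- sh_test(aln, list(a = tree, b = tree), model,
                  n_replicates = 200, seed = 5)
  expect_true(all(res3$p_value == 1))

  expect_error(sh_test(aln, trees, model, n_replicates = 50, seed = 1),
               "replicates")
})

test_that("a strongly contradicted topology is rejected by the SH test", {
  cfg <- test_config(n_taxa = 8, lengths = 3000, seed = 21)
  tree <- simulate_tree(cfg)
  aln <- evolve_alignment(tree, cfg)
  # alternative: shuffle tip labels, destroying all signal
  wrong <- tree
  set.seed(1)
  wrong$tip.label <- sample(tree$tip.label)
  res <- sh_test(aln, list(true = tree, wrong = wrong), cfg$model,
                 n_replicates = 500, seed = 77)
  expect_lt(res$p_value[res$tree_id == "wrong"], 0.01)
  expect_equal(res$p_value[res$tree_id == "true"], 1)
})

test_that("estimate_model returns a usable model with sane parameters", {
  cfg <- test_config(n_taxa = 8, lengths = 1200, seed = 30)
  tree <- simulate_tree(cfg)
  aln <- evolve_alignment(tree, cfg)
  m <- estimate_model(aln, tree)
  expect_s3_class(m, "substitution_model")
  expect_equal(sum(m$base_freqs), 1, tolerance = 1e-9)
  expect_true(m$p_invariant >= 0 && m$p_invariant <= 0.5)
  expect_true(is.finite(tree_log_likelihood(aln, tree, m)))
})
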