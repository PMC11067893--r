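test_that("simulation is deterministic given a seed and config", {
  cfg <- test_config(n_taxa = 10, lengths = c(300, 500), seed = 6)
  t1 <- simulate_tree(cfg); t2 <- simulate_tree(cfg)
  expect_equal(write_newick(t1), write_newick(t2))
  a1 <- evolve_alignment(t1, cfg); a2 <- evolve_alignment(t2, cfg)
  expect_identical(a1$seq, a2$seq)

  # different seed, different draw
  cfg2 <- test_config(n_taxa = 10, lengths = c(300, 500), seed = 7)
  expect_false(write_newick(simulate_tree(cfg2)) == write_newick(t1))

  # simulation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(evolve_alignment(t1, cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("simulated trees honour taxon count and height rescaling", {
  for (h in c(0.1, 0.3, 1)) {
    cfg <- test_config(n_taxa = 51, lengths = 100, seed = 3, tree_height = h)
    tr <- simulate_tree(cfg)
    expect_equal(ape::Ntip(tr), 51L)
    expect_equal(count_bifurcating_nodes(tr), 50L)
    expect_equal(max(ape::node.depth.edgelength(tr)), h, tolerance = 1e-9)
  }
})

test_that("evolved divergence matches the JC closed form on a long branch", {
  # two taxa at total separation t: expected p = 3/4 (1 - exp(-4t/3))
  tree <- ape::read.tree(text = "(a:0.15,b:0.15);")
  cfg <- test_config(n_taxa = 4, lengths = 50000, seed = 13)
  aln <- evolve_alignment(tree, cfg)
  p <- p_distance_matrix(aln)["a", "b"]
  t_tot <- 0.3
  expected <- 0.75 * (1 - exp(-4 * t_tot / 3))
  se <- sqrt(expected * (1 - expected) / 50000)
  expect_lt(abs(p - expected), 4 * se)

  # a very long branch saturates to p ~ 0.75
  long <- ape::read.tree(text = "(a:20,b:20);")
  alnl <- evolve_alignment(long, test_config(n_taxa = 4, lengths = 20000,
                                             seed = 14))
  expect_equal(p_distance_matrix(alnl)["a", "b"], 0.75, tolerance = 0.02)
})

test_that("stationary base frequencies are respected", {
  freqs <- c(0.4, 0.3, 0.1, 0.2)
  model <- substitution_model(base_freqs = freqs)
  tree <- ape::read.tree(text = "(a:0.5,b:0.5);")
  cfg <- test_config(n_taxa = 4, lengths = 50000, seed = 19, model = model)
  aln <- evolve_alignment(tree, cfg)
  obs <- table(factor(aln$seq, levels = c("A", "C", "G", "T")))
  chisq <- stats::chisq.test(obs, p = freqs)
  expect_gt(chisq$p.value, 0.001)
})

test_that("p_invariant = 1 yields a constant alignment", {
  model <- substitution_model(p_invariant = 1, gamma_shape = NULL)
  cfg <- test_config(n_taxa = 6, lengths = 200, seed = 23, model = model,
                     tree_height = 2)
  aln <- evolve_alignment(simulate_tree(cfg), cfg)
  expect_true(all(apply(aln$seq, 2L, function(col) length(unique(col)) == 1L)))
})

test_that("rate multipliers change per-partition divergence as expected", {
  cfg <- test_config(n_taxa = 4, lengths = c(20000, 20000), seed = 27,
                     rate_multipliers = c(0.2, 3))
  tree <- ape::read.tree(text = "(a:0.1,b:0.1);")
  aln <- evolve_alignment(tree, cfg)
  p_slow <- p_distance_matrix(extract_partition(aln, "g1"))["a", "b"]
  p_fast <- p_distance_matrix(extract_partition(aln, "g2"))["a", "b"]
  expect_lt(p_slow, p_fast)
  # slow partition should be near the closed form at 0.2 * 0.2
  exp_slow <- 0.75 * (1 - exp(-4 * 0.2 * 0.2 / 3))
  expect_lt(abs(p_slow - exp_slow), 5 * sqrt(exp_slow / 20000))
})

test_that("branch keys identify clades and NNI neighbours differ by RF 2", {
  ref <- balanced8()
  key <- branch_key(ref, c("A", "B"))
  expect_equal(key, split_key_for_test(c("A", "B"), LETTERS[1:8]))
  expect_true(key %in% names(nontrivial_bipartitions(ref)))
  expect_error(branch_key(ref, c("A", "C")), "not a nontrivial branch")

  set.seed(8)
  tr <- ape::rtree(12)
  for (e in 1:5) {
    nb <- nni_neighbor(tr, edge = e)
    expect_equal(rf_distance(tr, nb), 2)
  }
})

test_that("concordance fixtures hit requested per-branch fractions exactly", {
  ref <- balanced8()
  ab <- split_key_for_test(c("A", "B"), LETTERS[1:8])
  efgh <- split_key_for_test(c("E", "F", "G", "H"), LETTERS[1:8])
  fix <- make_concordance_fixture(ref, setNames(c(1 / 3, 0.8), c(ab, efgh)),
                                  n_trees = 15, seed = 91)
  expect_length(fix, 15L)
  has <- function(key) sum(vapply(fix, function(t)
    key %in% names(nontrivial_bipartitions(t)), logical(1)))
  expect_equal(has(ab), 5L)        # round(1/3 * 15)
  expect_equal(has(efgh), 12L)     # round(0.8 * 15)

  # unlisted branches stay present in every tree
  cd <- split_key_for_test(c("C", "D"), LETTERS[1:8])
  expect_equal(has(cd), 15L)

  # determinism
  fix2 <- make_concordance_fixture(ref, setNames(c(1 / 3, 0.8), c(ab, efgh)),
                                   n_trees = 15, seed = 91)
  expect_equal(lapply(fix, write_newick), lapply(fix2, write_newick))
})

test_that("NJ recovers a fixed 8-taxon tree from simulated alignments", {
  # fixed-tree recovery experiment: one identifiable topology, 100 seeded
  # alignment replicates (random Yule trees can carry near-zero internal
  # branches no estimator could resolve, so the tree is held fixed)
  tr <- read_newick(text = paste0(
    "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.05,",
    "((E:0.05,F:0.05):0.05,(G:0.05,H:0.05):0.05):0.05);"))
  hits <- 0L
  for (seed in 1:100) {
    cfg <- test_config(n_taxa = 8, lengths = 10000, seed = seed)
    aln <- evolve_alignment(tr, cfg, seed = seed)
    if (rf_distance(estimate_tree_nj(aln), tr) == 0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("write_simulated_study produces a complete, runnable bundle", {
  dir <- file.path(tempdir(), "study1")
  cfg <- test_config(n_taxa = 8, lengths = c(400, 600), seed = 37)
  paths <- write_simulated_study(dir, cfg)
  expect_true(file.exists(file.path(dir, "reference.nwk")))
  expect_true(file.exists(file.path(dir, "alignment.fasta")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "genes", "g1.fasta")))
  expect_true(file.exists(file.path(dir, "genes", "g2.nwk")))

  ref <- read_newick(file = file.path(dir, "reference.nwk"))
  aln <- read_fasta_alignment(file.path(dir, "alignment.fasta"))
  expect_setequal(ref$tip.label, taxa_names(aln))
  expect_equal(alignment_length(aln), 1000L)
  g1 <- read_fasta_alignment(file.path(dir, "genes", "g1.fasta"))
  expect_equal(alignment_length(g1), 400L)
  unlink(dir, recursive = TRUE)
})
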