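test_that("RF distance matches hand-worked examples and metric properties", {
  a <- read_newick(text = "((A,B),(C,D),E);")
  b <- read_newick(text = "((A,C),(B,D),E);")
  expect_equal(rf_distance(a, a), 0)
  expect_equal(rf_distance(a, b), 4)  # both nontrivial splits disagree

  # caterpillar vs one-NNI neighbour differs by exactly one split pair
  cat6 <- read_newick(text = "(((((A,B),C),D),E),F);")
  nn <- nni_neighbor(cat6, edge = 1)
  expect_equal(rf_distance(cat6, nn), 2)

  expect_error(rf_distance(a, read_newick(text = "((A,B),(C,X),E);")),
               "leaf sets differ")

  # symmetry + triangle inequality on random triples
  set.seed(9)
  for (i in 1:10) {
    trs <- lapply(1:3, function(k) ape::rtree(12))
    d12 <- rf_distance(trs[[1]], trs[[2]])
    expect_equal(d12, rf_distance(trs[[2]], trs[[1]]))
    expect_lte(d12, rf_distance(trs[[1]], trs[[3]]) + rf_distance(trs[[3]], trs[[2]]))
  }
})

test_that("RF distance agrees with phangorn over random tree pairs", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- ape::rtree(n); y <- ape::rtree(n)
    expect_equal(rf_distance(x, y),
                 as.integer(phangorn::RF.dist(x, y)))
  }
  # and with polytomies
  for (i in 1:20) {
    x <- ape::di2multi(ape::rtree(15), tol = 0.3)
    y <- ape::di2multi(ape::rtree(15), tol = 0.3)
    expect_equal(rf_distance(x, y), as.integer(phangorn::RF.dist(x, y)))
  }
})

test_that("rf_matrix is symmetric with zero diagonal", {
  set.seed(3)
  trees <- setNames(lapply(1:4, function(i) ape::rtree(10)),
                    paste0("g", 1:4))
  m <- rf_matrix(trees)
  expect_true(isSymmetric(unname(m)))
  expect_true(all(diag(m) == 0))
  expect_equal(m["g1", "g3"], rf_distance(trees$g1, trees$g3))
})

test_that("neighbor joining recovers additive distances exactly", {
  # classic additive 4-taxon matrix; internal branch 1
  d <- matrix(c(0, 3, 7, 8,
                3, 0, 8, 9,
                7, 8, 0, 7,
                8, 9, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  expect_equal(rf_distance(tr, read_newick(text = "((A,B),(C,D));")), 0)
  # recovered patristic distances reproduce the input exactly
  pat <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(unname(pat), unname(d), tolerance = 1e-10)
  expect_equal(tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "C")], 3)

  # random additive matrices from random trees are recovered exactly
  set.seed(18)
  for (i in 1:10) {
    true <- ape::rtree(sample(6:20, 1))
    true$edge.length <- runif(nrow(true$edge), 0.2, 1)
    dm <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(dm)
    expect_equal(rf_distance(est, true), 0)
    expect_equal(unname(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)]),
                 unname(dm), tolerance = 1e-8)
  }
})

test_that("neighbor joining matches ape::nj topologies on noisy matrices", {
  set.seed(27)
  for (i in 1:10) {
    true <- ape::rtree(12)
    true$edge.length <- runif(nrow(true$edge), 0.2, 1)
    dm <- ape::cophenetic.phylo(true)
    noise <- matrix(runif(length(dm), 0, 0.05), nrow(dm))
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    dm <- dm + noise
    expect_equal(rf_distance(neighbor_joining(dm), ape::nj(dm)), 0)
  }
  # negative branch estimates are clamped to zero and the deficit recorded
  dneg <- matrix(c(0, 1, 6, 6,
                   1, 0, 6, 6,
                   6, 6, 0, 1,
                   6, 6, 1, 0) / 10, 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(dneg)
  expect_true(all(tr$edge.length >= 0))
})

test_that("gene concordance factors count decisive gene trees per branch", {
  ref <- balanced8()
  keys <- names(nontrivial_bipartitions(ref))
  ab_key <- split_key_for_test(c("A", "B"), LETTERS[1:8])
  expect_true(ab_key %in% keys)

  # 5 of 15 decisive gene trees contain the AB branch -> 33.3
  fix <- make_concordance_fixture(ref, setNames(5 / 15, ab_key),
                                  n_trees = 15, seed = 42)
  gcf <- gene_concordance_factor(ref, fix)
  row <- gcf[gcf$branch == ab_key, ]
  expect_equal(row$gcf, 33.3)
  expect_equal(row$n_support, 5L)
  expect_equal(row$n_decisive, 15L)

  fix8 <- make_concordance_fixture(ref, setNames(8 / 15, ab_key),
                                   n_trees = 15, seed = 43)
  expect_equal(gene_concordance_factor(ref, fix8)[
    gene_concordance_factor(ref, fix8)$branch == ab_key, "gcf"], 53.3)

  # identical copies of the reference give 100 everywhere
  all100 <- gene_concordance_factor(ref, rep(list(ref), 7))
  expect_true(all(all100$gcf == 100))
  expect_true(all(all100$n_decisive == 7L))
})

test_that("gCF restricts to shared taxa and respects decisiveness", {
  ref <- balanced8()
  ab_key <- split_key_for_test(c("A", "B"), LETTERS[1:8])
  # a gene tree missing taxon B is indecisive for the AB branch
  # (restricted side has < 2 taxa) but still decisive elsewhere
  pruned <- ape::drop.tip(ref, "B")
  gcf <- gene_concordance_factor(ref, list(pruned, ref, ref))
  row <- gcf[gcf$branch == ab_key, ]
  expect_equal(row$n_decisive, 2L)
  expect_equal(row$gcf, 100)

  cd_key <- split_key_for_test(c("C", "D"), LETTERS[1:8])
  expect_equal(gcf[gcf$branch == cd_key, "n_decisive"], 3L)
})

test_that("site concordance factors behave on constructed alignments", {
  ref <- read_newick(text = "(((A,B),(C,D)),((E,F),(G,H)));")
  # alignment where every site cleanly supports the reference splits:
  # two-state columns separating {A..D} from {E..H}
  cols <- rep(list("AAAATTTT"), 200)
  aln <- aln_from_columns(cols, taxa = LETTERS[1:8])
  scf <- site_concordance_factor(ref, aln, n_quartets = 50, seed = 7)
  root_key <- split_key_for_test(LETTERS[5:8], LETTERS[1:8])
  expect_equal(scf[scf$branch == root_key, "scf"], 100)

  # determinism under the same seed
  scf2 <- site_concordance_factor(ref, aln, n_quartets = 50, seed = 7)
  expect_identical(scf, scf2)

  # random noise alignment: supporting quartet pattern is one of three
  # resolutions, so sCF should sit near 33.3 on the root branch
  r <- random_alignment(8, 5000, seed = 101)
  rownames(r$seq) <- LETTERS[1:8]
  rn <- dna_alignment(r$seq)
  scf_r <- site_concordance_factor(ref, rn, n_quartets = 200, seed = 11)
  val <- scf_r[scf_r$branch == root_key, "scf"]
  expect_gt(val, 20)
  expect_lt(val, 47)
})

test_that("annotate_concordance writes gcf or gcf/scf node labels", {
  ref <- balanced8()
  fix <- rep(list(ref), 4)
  gcf <- gene_concordance_factor(ref, fix)
  ann <- annotate_concordance(ref, gcf)
  labs <- ann$node.label[ann$node.label != ""]
  expect_true(all(labs == "100.0"))

  aln <- aln_from_columns(rep(list("AAAATTTT"), 100), taxa = LETTERS[1:8])
  scf <- site_concordance_factor(ref, aln, n_quartets = 20, seed = 3)
  ann2 <- annotate_concordance(ref, gcf, scf)
  expect_true(any(grepl("^100\\.0/", ann2$node.label)))
})
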