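# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# small resolved rooted tree with supports on every internal node
balanced8 <- function() {
  read_newick(text = paste0(
    "(((A:1,B:1)0.9:1,(C:1,D:1)1:1)0.95:1,",
    "((E:1,F:1)0.8:1,(G:1,H:1)0.99:1)0.7:1);"))
}

# alignment from explicit columns (rows named t1..tn)
aln_from_columns <- function(cols, taxa = NULL) {
  m <- do.call(cbind, lapply(cols, function(s) strsplit(s, "")[[1L]]))
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(m)))
  rownames(m) <- taxa
  dna_alignment(m)
}

# seeded random alignment over ACGT with optional gap/ambiguity noise
random_alignment <- function(n_taxa, n_sites, seed, miss_frac = 0) {
  set.seed(seed)
  pool <- c("A", "C", "G", "T")
  m <- matrix(sample(pool, n_taxa * n_sites, replace = TRUE),
              nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  if (miss_frac > 0) {
    k <- round(miss_frac * length(m))
    m[sample(length(m), k)] <- sample(c("-", "N", "R", "Y"), k, replace = TRUE)
  }
  dna_alignment(m)
}

# independent brute-force PI-site oracle (per-column tally, written
# without reference to the package's implementation)
oracle_pi_count <- function(aln) {
  sum(apply(aln$seq, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    counts <- table(col)
    sum(counts >= 2) >= 2
  }))
}

# independent p-distance oracle: double loop over pairs and sites
oracle_p_distance <- function(aln) {
  n <- nrow(aln$seq)
  d <- matrix(0, n, n, dimnames = list(rownames(aln$seq), rownames(aln$seq)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diffs <- 0L; comp <- 0L
    for (s in seq_len(ncol(aln$seq))) {
      a <- aln$seq[i, s]; b <- aln$seq[j, s]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        comp <- comp + 1L
        if (a != b) diffs <- diffs + 1L
      }
    }
    d[i, j] <- if (comp == 0L) NA_real_ else diffs / comp
  }
  d
}

# Independent exhaustive-likelihood oracle: enumerate all internal-node
# state assignments and sum products of transition probabilities. Builds
# its own GTR transition matrices from scratch (eigen of the raw Q).
oracle_loglik <- function(aln, tree, rates, freqs) {
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (r in seq_len(6)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    Q[i, j] <- rates[r] * freqs[j]
    Q[j, i] <- rates[r] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(freqs * diag(Q))
  pmat <- function(t) {
    e <- eigen(Q)
    Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  }
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  P <- lapply(seq_len(nrow(tree$edge)), function(k) pmat(tree$edge.length[k]))
  tipstate <- match(aln$seq[tree$tip.label, , drop = FALSE], bases)
  dim(tipstate) <- dim(aln$seq)
  total <- 0
  for (s in seq_len(ncol(aln$seq))) {
    lik <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), n_node)))
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(v) {
        if (v <= n_tip) tipstate[v, s] else grid[g, v - n_tip]
      }
      term <- freqs[grid[g, 1]]
      for (k in seq_len(nrow(tree$edge))) {
        term <- term * P[[k]][assign_state(tree$edge[k, 1]),
                              assign_state(tree$edge[k, 2])]
      }
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# expected canonical split key, computed independently of the package
split_key_for_test <- function(side, taxa) {
  anchor <- min(taxa)
  if (anchor %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = "\r")
}

# default simulation config at test scale
test_config <- function(n_taxa = 8, lengths = 1000, seed = 1,
                        model = substitution_model(), ...) {
  simulation_config(
    n_taxa = n_taxa,
    partitions = data.frame(gene = paste0("g", seq_along(lengths)),
                            length = lengths),
    model = model, seed = seed, ...)
}
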