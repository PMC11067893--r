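# Site likelihoods under GTR+I+G by Felsenstein pruning, single-branch
# likelihood optimization, and the Shimodaira-Hasegawa topology test with
# RELL resampling.

.IUPAC <- list(
  A = 1L, C = 2L, G = 3L, T = 4L,
  R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L), W = c(1L, 4L),
  K = c(3L, 4L), M = c(1L, 2L),
  B = c(2L, 3L, 4L), D = c(1L, 3L, 4L), H = c(1L, 2L, 4L), V = c(1L, 2L, 3L),
  N = 1:4, `-` = 1:4, `?` = 1:4, `.` = 1:4)

#' GTR+I+G substitution model
#'
#' General time-reversible rate matrix with optional invariant-sites
#' proportion and discrete-gamma rate heterogeneity. The rate matrix is
#' scaled to one expected substitution per site per unit branch length,
#' and the discrete rate classes (gamma categories scaled by
#' `1/(1 - p_invariant)`, plus a zero-rate invariant class) keep the mean
#' rate at 1, so branch lengths stay in substitutions/site.
#'
#' @param rates Six non-negative GTR exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT (scale-free).
#' @param base_freqs Four equilibrium base frequencies (A, C, G, T),
#'   summing to 1.
#' @param p_invariant Proportion of invariant sites, in \[0, 1\]. The
#'   boundary value 1 (all sites invariant) is accepted for simulation
#'   use; likelihoods then assign probability 0 to non-constant patterns.
#' @param gamma_shape Gamma shape `alpha`; `NULL` disables rate
#'   heterogeneity.
#' @param n_categories Number of discrete gamma categories (default 4),
#'   discretized by the mean of each quantile section.
#' @return An object of class `"substitution_model"`.
#' @export
substitution_model <- function(rates = rep(1, 6), base_freqs = rep(0.25, 4),
                               p_invariant = 0, gamma_shape = NULL,
                               n_categories = 4L) {
  stopifnot(length(rates) == 6L, all(rates >= 0), any(rates > 0),
            length(base_freqs) == 4L, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8,
            p_invariant >= 0, p_invariant <= 1)
  if (!is.null(gamma_shape))
    stopifnot(is.finite(gamma_shape), gamma_shape > 0, n_categories >= 1L)
  pi <- base_freqs / sum(base_freqs)
  S <- matrix(0, 4, 4)
  # column-major lower triangle is (CA, GA, TA, GC, TC, TG) = input order
  S[lower.tri(S)] <- rates
  S <- S + t(S)
  Q <- S * rep(pi, each = 4L)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # eigen-decomposition of the symmetrized matrix: guaranteed real
  sq <- sqrt(pi)
  B <- Q * outer(sq, 1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  model <- structure(list(
    rates = rates / max(rates), base_freqs = pi,
    p_invariant = p_invariant, gamma_shape = gamma_shape,
    n_categories = if (is.null(gamma_shape)) 1L else as.integer(n_categories),
    Q = Q,
    eig = list(values = e$values,
               left = (1 / sq) * e$vectors,          # diag(1/sq) %*% V
               right = t(e$vectors * sq))),          # t(V) %*% diag(sq)
    class = "substitution_model")
  model
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("GTR substitution model\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      paste(signif(x$rates, 4), collapse = " "), "\n")
  cat("  base frequencies:", paste(signif(x$base_freqs, 4), collapse = " "), "\n")
  cat("  p_invariant:", x$p_invariant,
      " gamma shape:", if (is.null(x$gamma_shape)) "none" else x$gamma_shape,
      " categories:", x$n_categories, "\n")
  invisible(x)
}

#' Discrete gamma category rates (mean of quantile sections)
#'
#' @param alpha Gamma shape (rate parameter equal to shape, so the mean
#'   is 1).
#' @param k Number of categories.
#' @return Numeric vector of `k` category rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  upper <- stats::pgamma(bounds[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(bounds[-(k + 1L)], shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

# rate classes (rate, weight) including the invariant class; mean rate 1
rate_classes <- function(model) {
  p_inv <- model$p_invariant
  # boundary case used by the simulator: everything invariant
  if (p_inv >= 1) return(data.frame(rate = 0, weight = 1))
  if (is.null(model$gamma_shape)) {
    r <- 1
  } else {
    r <- discrete_gamma_rates(model$gamma_shape, model$n_categories)
  }
  k <- length(r)
  rates <- r / (1 - p_inv)
  weights <- rep((1 - p_inv) / k, k)
  if (p_inv > 0) {
    rates <- c(0, rates)
    weights <- c(p_inv, weights)
  }
  data.frame(rate = rates, weight = weights)
}

#' Transition probability matrix P(t)
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions per site, rate 1).
#' @return 4x4 stochastic matrix.
#' @export
transition_probability <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$eig$left %*% (exp(model$eig$values * t) * model$eig$right)
  P[P < 0] <- 0
  P / rowSums(P)
}

# --- pruning machinery ------------------------------------------------

# compressed site patterns: list(codes = taxa x npat integer-free char
# matrix, weight = counts, index = per-site pattern id)
.compress_patterns <- function(m) {
  pat <- apply(m, 2L, paste, collapse = "")
  u <- unique(pat)
  idx <- match(pat, u)
  list(cols = match(u, pat), weight = tabulate(idx, nbins = length(u)),
       index = idx)
}

# tip partial likelihood arrays: list per tip of 4 x npat matrices
.tip_partials <- function(m, cols) {
  lapply(seq_len(nrow(m)), function(i) {
    out <- matrix(0, 4L, length(cols))
    ch <- m[i, cols]
    for (j in seq_along(cols)) {
      comp <- .IUPAC[[ch[j]]]
      if (is.null(comp)) stop("unrecognized base '", ch[j], "'")
      out[comp, j] <- 1
    }
    out
  })
}

# log-likelihood per pattern for given edge lengths; `st` is the cached
# structure built by .ll_structure
.pattern_likelihood <- function(st, elens, model) {
  classes <- rate_classes(model)
  lik <- numeric(st$npat)
  for (ci in seq_len(nrow(classes))) {
    r <- classes$rate[ci]
    P <- lapply(elens * r, transition_probability, model = model)
    part <- vector("list", st$n_all)
    for (k in seq_along(st$po_parent)) {
      p <- st$po_parent[k]; ch <- st$po_child[k]
      down <- if (ch <= st$n_tip) st$tipp[[ch]] else part[[ch]]
      contrib <- P[[st$po_edge[k]]] %*% down  # L_p[x] = sum_y P_xy L_child[y]
      part[[p]] <- if (is.null(part[[p]])) contrib else part[[p]] * contrib
    }
    lik <- lik + classes$weight[ci] *
      colSums(model$base_freqs * part[[st$root]])
  }
  lik
}

.ll_structure <- function(aln, tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (!setequal(tree$tip.label, rownames(aln$seq)))
    stop("taxa mismatch between tree and alignment")
  m <- aln$seq[tree$tip.label, , drop = FALSE]
  cp <- .compress_patterns(m)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  edge_id <- match(paste(po[, 1L], po[, 2L]),
                   paste(tree$edge[, 1L], tree$edge[, 2L]))
  list(n_tip = ape::Ntip(tree), n_all = ape::Ntip(tree) + tree$Nnode,
       root = ape::Ntip(tree) + 1L,
       po_parent = po[, 1L], po_child = po[, 2L], po_edge = edge_id,
       tipp = .tip_partials(m, cp$cols), npat = length(cp$weight),
       weight = cp$weight, index = cp$index)
}

#' Per-site log-likelihoods under a substitution model
#'
#' Felsenstein pruning over the tree, mixing the model's discrete rate
#' classes (gamma categories and the invariant class). Gaps and IUPAC
#' ambiguity codes enter as partial states with all compatible bases
#' equally likely.
#'
#' @param aln A [dna_alignment()] whose taxa match the tree's leaves.
#' @param tree `phylo` with branch lengths.
#' @param model A [substitution_model()].
#' @return Numeric vector, one log-likelihood per alignment column.
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  st <- .ll_structure(aln, tree)
  lik <- .pattern_likelihood(st, tree$edge.length, model)
  log(lik)[st$index]
}

#' Total tree log-likelihood
#'
#' @inheritParams site_log_likelihoods
#' @return Sum of [site_log_likelihoods()] over columns.
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  st <- .ll_structure(aln, tree)
  sum(st$weight * log(.pattern_likelihood(st, tree$edge.length, model)))
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise optimization: each branch in turn is optimized by a
#' bounded golden-section/parabolic search with all others held fixed,
#' sweeping over the branches until the total log-likelihood improves by
#' less than `tol`. The log-likelihood is non-decreasing across sweeps by
#' construction.
#'
#' @inheritParams site_log_likelihoods
#' @param tol Convergence tolerance on the log-likelihood (default 1e-4).
#' @param max_sweeps Sweep cap; non-convergence returns the last iterate
#'   with a warning and attributes `converged = FALSE`,
#'   `last_improvement`.
#' @param max_branch Upper search bound per branch (substitutions/site).
#' @return The tree with optimized `$edge.length`; attributes `loglik`,
#'   `converged`, `sweeps`, `last_improvement`.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-4,
                                    max_sweeps = 30L, max_branch = 10) {
  st <- .ll_structure(aln, tree)
  elens <- tree$edge.length
  elens[elens < 1e-8] <- 1e-8
  ll <- function(e) sum(st$weight * log(.pattern_likelihood(st, e, model)))
  cur <- ll(elens)
  improvement <- Inf
  sweeps <- 0L
  while (improvement >= tol && sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    prev <- cur
    for (i in seq_along(elens)) {
      f <- function(x) { e <- elens; e[i] <- x; ll(e) }
      opt <- stats::optimize(f, c(1e-8, max(max_branch, 2 * elens[i])),
                             maximum = TRUE, tol = 1e-7)
      if (opt$objective > cur) {
        elens[i] <- opt$maximum
        cur <- opt$objective
      }
    }
    improvement <- cur - prev
  }
  converged <- improvement < tol
  if (!converged)
    warning("branch-length optimization did not converge; last improvement ",
            signif(improvement, 3))
  tree$edge.length <- elens
  attr(tree, "loglik") <- cur
  attr(tree, "converged") <- converged
  attr(tree, "sweeps") <- sweeps
  attr(tree, "last_improvement") <- improvement
  tree
}

#' Shimodaira-Hasegawa topology test with RELL resampling
#'
#' Classic SH procedure: per-site log-likelihoods for every candidate
#' topology are resampled with replacement (`RELL`) `n_replicates` times;
#' each tree's replicate log-likelihoods are centered on that tree's
#' replicate mean; within each replicate every tree's deficit from the
#' replicate-best tree is computed; the p-value of tree i is the
#' proportion of replicates whose centered deficit is at least the
#' observed deficit of tree i. The maximum-likelihood tree gets p = 1 by
#' construction.
#'
#' @param aln Test alignment (a [dna_alignment()]).
#' @param trees Named list of candidate `phylo` topologies.
#' @param model A [substitution_model()].
#' @param n_replicates RELL bootstrap replicates (default 1000; fewer
#'   than 100 is refused unless `allow_few_replicates = TRUE`).
#' @param seed Integer seed (mandatory).
#' @param optimize Re-optimize branch lengths per topology on `aln`
#'   before scoring (default `TRUE`; set `FALSE` when the supplied trees
#'   already carry optimized lengths).
#' @param allow_few_replicates Override the replicate floor.
#' @return `data.frame` of class `"sh_test_result"` with columns
#'   `tree_id`, `log_likelihood`, `delta`, `p_value`; attributes
#'   `n_replicates` and `seed`.
#' @export
sh_test <- function(aln, trees, model, n_replicates = 1000L, seed,
                    optimize = TRUE, allow_few_replicates = FALSE) {
  stopifnot(is.list(trees), length(trees) >= 2L)
  if (missing(seed)) stop("`seed` is required")
  if (n_replicates < 100L && !allow_few_replicates)
    stop("n_replicates < 100 gives an underpowered test; set allow_few_replicates = TRUE to override")
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- paste0("tree", seq_along(trees))
  site_ll <- vapply(trees, function(t) {
    if (optimize) t <- optimize_branch_lengths(aln, t, model)
    site_log_likelihoods(aln, t, model)
  }, numeric(ncol(aln$seq)))
  lnl <- colSums(site_ll)
  delta <- max(lnl) - lnl
  n_sites <- nrow(site_ll)
  p <- with_seed(seed, {
    w <- stats::rmultinom(n_replicates, n_sites, rep(1 / n_sites, n_sites))
    repl <- crossprod(site_ll, w)              # trees x replicates
    centered <- repl - rowMeans(repl)
    best <- apply(centered, 2L, max)
    deficit <- sweep(-centered, 2L, best, "+") # best - centered, per replicate
    vapply(seq_along(lnl), function(i)
      mean(deficit[i, ] >= delta[i] - 1e-9), numeric(1L))
  })
  out <- data.frame(tree_id = names(trees), log_likelihood = lnl,
                    delta = delta, p_value = p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_replicates") <- n_replicates
  attr(out, "seed") <- seed
  class(out) <- c("sh_test_result", class(out))
  out
}

#' Quick model fit heuristics for a fixed tree
#'
#' Empirical defaults when no externally estimated model is supplied:
#' base frequencies from the alignment, invariant proportion from the
#' constant-site fraction (capped at 0.5), and gamma shape picked from a
#' coarse grid by likelihood on the given tree.
#'
#' @param aln A [dna_alignment()].
#' @param tree `phylo` with branch lengths (used only to score the grid).
#' @param shape_grid Candidate gamma shapes.
#' @return A [substitution_model()].
#' @export
estimate_model <- function(aln, tree,
                           shape_grid = c(0.25, 0.5, 1, 2, 4)) {
  code <- .base_codes(aln)
  f <- tabulate(code, nbins = 4L)
  bf <- (f + 1) / (sum(f) + 4)
  const <- mean(apply(aln$seq, 2L, function(col) {
    b <- unique(col[col %in% .BASES])
    length(b) <= 1L
  }))
  p_inv <- min(const, 0.5)
  fits <- vapply(shape_grid, function(a) {
    m <- substitution_model(base_freqs = bf, p_invariant = p_inv,
                            gamma_shape = a)
    tree_log_likelihood(aln, tree, m)
  }, numeric(1L))
  substitution_model(base_freqs = bf, p_invariant = p_inv,
                     gamma_shape = shape_grid[which.max(fits)])
}
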