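# Tree-to-tree congruence: Robinson-Foulds distances, the NJ dendrogram
# over a topological distance matrix, and gene/site concordance factors
# on the branches of a reference tree.

#' Robinson-Foulds distance between two trees
#'
#' Cardinality of the symmetric difference of the nontrivial bipartition
#' sets of the two trees after unrooting (unweighted RF). Zero iff the
#' unrooted topologies are identical; at most `2(n-3)` for two binary
#' trees. No normalization is applied, so partially resolved trees can
#' yield odd values.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return Integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    only1 <- setdiff(t1$tip.label, t2$tip.label)
    only2 <- setdiff(t2$tip.label, t1$tip.label)
    stop("leaf sets differ; only in first: {",
         paste(only1, collapse = ", "), "}; only in second: {",
         paste(only2, collapse = ", "), "}")
  }
  k1 <- names(nontrivial_bipartitions(t1))
  k2 <- names(nontrivial_bipartitions(t2))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Pairwise RF distance matrix for a set of trees
#'
#' @param trees Named list of `phylo` objects on a shared leaf set.
#' @return Symmetric integer matrix with zero diagonal, labelled by the
#'   tree names.
#' @export
rf_matrix <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 3L)
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    stop("trees must be named")
  keys <- lapply(trees, function(t) names(nontrivial_bipartitions(t)))
  n <- length(trees)
  d <- matrix(0L, n, n, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(n - 1L)) {
    if (!setequal(trees[[i]]$tip.label, trees[[i + 1L]]$tip.label))
      stop("leaf sets differ between trees '", names(trees)[i],
           "' and '", names(trees)[i + 1L], "'")
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- length(setdiff(keys[[i]], keys[[j]])) +
      length(setdiff(keys[[j]], keys[[i]]))
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion. Ties in
#' the Q matrix are broken deterministically at the lowest (row, column)
#' index pair. Estimated negative branch lengths are clamped to zero and
#' the total clamped amount recorded in the `"clamped_deficit"`
#' attribute. Exact on additive matrices.
#'
#' @param d Symmetric numeric matrix (zero diagonal, finite non-negative
#'   entries) with row/column names.
#' @return Unrooted `phylo` over the labels of `d`.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (any(d < 0)) stop("distance matrix has negative entries")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 labels")

  lab <- rownames(d)
  # each active node is a newick fragment (subtree), joined pairwise
  frag <- .quote_newick_labels(lab)
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)

  while (n > 3L) {
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    # deterministic tie-break: smallest (i, j), i < j, among minima
    best <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    vi <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))))
    newfrag <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":", fmt(vj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(d2) <- colnames(d2) <- seq_len(n - 1L)
    d <- d2
    n <- n - 1L
  }
  va <- clamp((d[1L, 2L] + d[1L, 3L] - d[2L, 3L]) / 2)
  vb <- clamp((d[1L, 2L] + d[2L, 3L] - d[1L, 3L]) / 2)
  vc <- clamp((d[1L, 3L] + d[2L, 3L] - d[1L, 2L]) / 2)
  nwk <- paste0("(", frag[1L], ":", fmt(va), ",", frag[2L], ":", fmt(vb),
                ",", frag[3L], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

.quote_newick_labels <- function(lab) {
  needs <- grepl("[ \t(),:;'\\[\\]]", lab)
  lab[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
  lab
}

#' Gene concordance factors on a reference tree
#'
#' For every internal (nontrivial) branch of the reference tree, the
#' percentage of gene trees containing that branch among the gene trees
#' decisive for it. A gene tree missing some taxa is compared on the
#' shared taxa: the reference split is restricted to the gene tree's leaf
#' set and the gene tree is decisive only when both restricted sides keep
#' at least two taxa.
#'
#' @param reference `phylo`; its internal branches are annotated.
#' @param gene_trees Named list of `phylo` objects; leaf sets must be
#'   subsets of the reference leaf set.
#' @return `data.frame` of class `"concordance_table"`: one row per
#'   nontrivial reference branch with columns `branch` (canonical split
#'   key), `clade` (smaller side, space-separated), `gcf` (percentage,
#'   reported to one decimal; the exact ratio is recoverable from the
#'   counts), `n_support`, `n_decisive`, `n_gene_trees`.
#' @export
gene_concordance_factor <- function(reference, gene_trees) {
  stopifnot(inherits(reference, "phylo"))
  if (!length(gene_trees)) stop("no gene trees supplied")
  taxa <- sort(reference$tip.label)
  for (g in gene_trees)
    if (length(setdiff(g$tip.label, taxa)))
      stop("gene tree has taxa absent from the reference: ",
           paste(setdiff(g$tip.label, taxa), collapse = ", "))
  ref_splits <- nontrivial_bipartitions(reference)
  gene_info <- lapply(gene_trees, function(g) {
    list(taxa = sort(g$tip.label),
         keys = if (ape::Ntip(g) >= 4L) names(nontrivial_bipartitions(g))
                else character(0))
  })
  rows <- lapply(names(ref_splits), function(key) {
    side <- ref_splits[[key]]
    other <- setdiff(taxa, side)
    n_sup <- 0L; n_dec <- 0L
    for (gi in gene_info) {
      a <- intersect(side, gi$taxa); b <- intersect(other, gi$taxa)
      if (length(a) < 2L || length(b) < 2L) next
      n_dec <- n_dec + 1L
      if (split_key(a, gi$taxa) %in% gi$keys) n_sup <- n_sup + 1L
    }
    small <- if (length(side) <= length(other)) side else other
    data.frame(branch = key,
               clade = paste(small, collapse = " "),
               gcf = if (n_dec) round(100 * n_sup / n_dec, 1L) else NA_real_,
               n_support = n_sup, n_decisive = n_dec,
               n_gene_trees = length(gene_info),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("concordance_table", class(out))
  out
}

# tip labels beyond `to`, looking from `from`, in an adjacency list
.tips_beyond <- function(adj, tip_label, from, to) {
  seen <- c(from, to)
  stack <- to
  tips <- character(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (!is.na(tip_label[v])) tips <- c(tips, tip_label[v])
    nb <- setdiff(adj[[v]], seen)
    seen <- c(seen, nb)
    stack <- c(stack, nb)
  }
  tips
}

#' Site concordance factors on a reference tree
#'
#' For each internal branch of the unrooted reference, quartets are
#' sampled around the branch (one leaf from each of two distinct subtrees
#' on either end), and each alignment column where all four sampled
#' leaves carry unambiguous bases is classified as supporting one of the
#' three quartet topologies when it shows a clean two-state 2+2 pattern.
#' The branch sCF is the mean, over sampled quartets with at least one
#' decisive site, of `100 * sites supporting the reference quartet /
#' sites supporting any topology`.
#'
#' @param reference `phylo` on the alignment's taxa.
#' @param aln A [dna_alignment()] covering the reference leaf set.
#' @param n_quartets Quartets sampled per branch (default 100).
#' @param seed Integer seed (mandatory for reproducible sampling).
#' @return `data.frame`: `branch` key, `clade`, `scf`,
#'   `n_quartets_sampled`, `n_quartets_decisive`.
#' @export
site_concordance_factor <- function(reference, aln, n_quartets = 100L, seed) {
  stopifnot(inherits(reference, "phylo"), inherits(aln, "dna_alignment"))
  if (missing(seed)) stop("`seed` is required")
  missing_taxa <- setdiff(reference$tip.label, rownames(aln$seq))
  if (length(missing_taxa))
    stop("alignment lacks taxa: ", paste(missing_taxa, collapse = ", "))
  ut <- ape::unroot(reference)
  n_tip <- ape::Ntip(ut)
  n_all <- n_tip + ut$Nnode
  tip_label <- c(ut$tip.label, rep(NA_character_, ut$Nnode))
  adj <- vector("list", n_all)
  for (k in seq_len(nrow(ut$edge))) {
    a <- ut$edge[k, 1L]; b <- ut$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  code <- .base_codes(aln)[ut$tip.label, , drop = FALSE]
  taxa <- sort(ut$tip.label)
  splits <- nontrivial_bipartitions(ut)

  internal_edges <- which(ut$edge[, 2L] > n_tip)
  with_seed(seed, {
    rows <- lapply(internal_edges, function(k) {
      u <- ut$edge[k, 1L]; v <- ut$edge[k, 2L]
      groups_u <- lapply(setdiff(adj[[u]], v), function(w)
        .tips_beyond(adj, tip_label, u, w))
      groups_v <- lapply(setdiff(adj[[v]], u), function(w)
        .tips_beyond(adj, tip_label, v, w))
      clade <- sort(unlist(groups_v))
      key <- split_key(clade, taxa)
      if (length(clade) < 2L || length(clade) > n_tip - 2L) return(NULL)
      if (length(groups_u) < 2L || length(groups_v) < 2L) return(NULL)
      vals <- numeric(0); n_dec <- 0L
      for (q in seq_len(n_quartets)) {
        gu <- sample.int(length(groups_u), 2L)
        gv <- sample.int(length(groups_v), 2L)
        a <- .sample1(groups_u[[gu[1L]]]); b <- .sample1(groups_u[[gu[2L]]])
        cc <- .sample1(groups_v[[gv[1L]]]); dd <- .sample1(groups_v[[gv[2L]]])
        xa <- code[a, ]; xb <- code[b, ]; xc <- code[cc, ]; xd <- code[dd, ]
        ok <- !(is.na(xa) | is.na(xb) | is.na(xc) | is.na(xd))
        if (!any(ok)) next
        xa <- xa[ok]; xb <- xb[ok]; xc <- xc[ok]; xd <- xd[ok]
        s_ref <- sum(xa == xb & xc == xd & xa != xc)
        s_alt1 <- sum(xa == xc & xb == xd & xa != xb)
        s_alt2 <- sum(xa == xd & xb == xc & xa != xb)
        tot <- s_ref + s_alt1 + s_alt2
        if (tot == 0L) next
        n_dec <- n_dec + 1L
        vals <- c(vals, 100 * s_ref / tot)
      }
      smaller <- if (length(clade) <= n_tip / 2) clade else setdiff(taxa, clade)
      data.frame(branch = key,
                 clade = paste(smaller, collapse = " "),
                 scf = if (n_dec) mean(vals) else NA_real_,
                 n_quartets_sampled = n_quartets,
                 n_quartets_decisive = n_dec,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("reference has no internal branch with four surrounding subtrees")
    out <- out[match(intersect(names(splits), out$branch), out$branch), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

.sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' Annotate a reference tree with concordance factors
#'
#' Writes gCF (and optionally sCF) into the internal-node label position
#' as `"gcf"` or `"gcf/scf"`, so the annotated tree can be exported as
#' Newick.
#'
#' @param reference `phylo`.
#' @param gcf Output of [gene_concordance_factor()].
#' @param scf Optional output of [site_concordance_factor()].
#' @return The reference tree with annotated `$node.label`.
#' @export
annotate_concordance <- function(reference, gcf, scf = NULL) {
  taxa <- sort(reference$tip.label)
  n_tip <- ape::Ntip(reference)
  sets <- .node_tipsets(reference)
  labels <- rep("", reference$Nnode)
  for (node in (n_tip + 1L):(n_tip + reference$Nnode)) {
    clade <- sets[[node]]
    if (length(clade) < 2L || length(clade) > n_tip - 2L) next
    key <- split_key(clade, taxa)
    i <- match(key, gcf$branch)
    if (is.na(i)) next
    lab <- sprintf("%.1f", gcf$gcf[i])
    if (!is.null(scf)) {
      j <- match(key, scf$branch)
      if (!is.na(j) && is.finite(scf$scf[j]))
        lab <- paste0(lab, "/", sprintf("%.1f", scf$scf[j]))
    }
    labels[node - n_tip] <- lab
  }
  reference$node.label <- labels
  reference
}
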