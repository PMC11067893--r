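#' Read a support-annotated Newick tree
#'
#' Parses a Newick string (or file) into an [ape::phylo] object, treating
#' internal-node annotations as statistical support values. Two encodings
#' are understood: the consensus-tree convention where supports sit in the
#' internal-node label position (`"((A,B)0.95,C);"`, the MrBayes/IQ-TREE
#' style) and the comment convention where they sit in square brackets
#' after the closing parenthesis (`"((A,B)[0.95],C);"`).
#'
#' The support scale is auto-detected per tree: values all within \[0, 1\]
#' are taken as posterior probabilities, anything larger as bootstrap
#' percentages; the detected scale is stored in the `"support_scale"`
#' attribute (`"pp"`, `"bootstrap"`, or `"none"`).
#'
#' @param text Newick string. Exactly one of `text`/`file` must be given.
#' @param file Path to a file whose first tree is read.
#' @param support `"node-label"` (default) or `"comment"`.
#' @return A `phylo` object; internal-node supports, where present, are in
#'   `$node.label` and available numerically via [node_supports()].
#' @seealso [write_newick()], [node_supports()]
#' @export
read_newick <- function(text = NULL, file = NULL,
                        support = c("node-label", "comment")) {
  support <- match.arg(support)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)

  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("malformed Newick: %d '(' but %d ')'", n_open, n_close))

  if (support == "comment") {
    # lift ")[0.95]" / ")[&support=0.95]" into the node-label position
    text <- gsub("\\)\\[&?(?:support=)?([0-9.eE+-]+)\\]", ")\\1", text)
  }
  # any remaining bracketed comments are metadata we do not interpret
  text <- gsub("\\[[^]]*\\]", "", text)

  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick: ape failed to parse the string")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    bad <- lab != "" & !is.na(lab) &
      is.na(suppressWarnings(as.numeric(lab)))
    if (any(bad))
      stop("non-numeric internal-node support label: '", lab[bad][1L], "'")
  }
  attr(tree, "support_scale") <- .detect_support_scale(tree)
  tree
}

#' Write a tree as Newick
#'
#' Inverse of [read_newick()]: internal-node supports are written in the
#' node-label position. Round-trips topology, branch lengths (to printed
#' precision) and supports.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `file`.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read the trees block of a NEXUS file
#'
#' Read-only NEXUS support: each tree is returned through the same
#' support-label interpretation as [read_newick()].
#'
#' @param file Path to a NEXUS file.
#' @return A named list of `phylo` objects.
#' @export
read_nexus_trees <- function(file) {
  trees <- ape::read.nexus(file)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), names = "tree1")
  lapply(trees, function(t) {
    attr(t, "support_scale") <- .detect_support_scale(t)
    t
  })
}

.detect_support_scale <- function(tree) {
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup <- sup[!is.na(sup)]
  if (!length(sup)) return("none")
  if (max(sup) <= 1) "pp" else "bootstrap"
}

#' Numeric node supports of a tree
#'
#' @param tree A `phylo` object with supports in `$node.label`.
#' @return Numeric vector of length `tree$Nnode`, `NA` where an internal
#'   node carries no annotation, with attribute `"scale"` (`"pp"`,
#'   `"bootstrap"` or `"none"`).
#' @export
node_supports <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) {
    sup <- rep(NA_real_, tree$Nnode)
  } else {
    sup <- suppressWarnings(as.numeric(tree$node.label))
  }
  structure(sup, scale = .detect_support_scale(tree))
}

#' Mean support over annotated internal nodes
#'
#' Arithmetic mean of the support values that are actually present on the
#' tree. Nodes without an annotation -- typically nodes collapsed into
#' polytomies on a consensus tree -- are excluded, so the statistic reads
#' "mean support of the supported nodes" and must be interpreted together
#' with the polytomy count.
#'
#' @param tree A `phylo` object.
#' @return The mean support (scale as stored on the tree).
#' @export
mean_node_support <- function(tree) {
  sup <- node_supports(tree)
  sup <- sup[!is.na(sup)]
  if (!length(sup)) stop("no supported nodes: tree carries no support annotations")
  mean(sup)
}

#' Count branches emanating from polytomies
#'
#' Sum, over internal nodes with more than two children (in the rooted
#' orientation as stored), of the number of child branches. A fully
#' bifurcating tree scores 0.
#'
#' @param tree A `phylo` object.
#' @return Integer count.
#' @export
count_polytomy_branches <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  kids <- tabulate(tree$edge[, 1L], nbins = ape::Ntip(tree) + tree$Nnode)
  as.integer(sum(kids[kids > 2L]))
}

#' Count fully bifurcating internal nodes
#'
#' Number of internal nodes with exactly two children, in the rooted
#' orientation as stored (the root counts when it is binary). A fully
#' resolved rooted tree on n leaves scores n - 1.
#'
#' @param tree A `phylo` object.
#' @return Integer count.
#' @export
count_bifurcating_nodes <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  kids <- tabulate(tree$edge[, 1L], nbins = ape::Ntip(tree) + tree$Nnode)
  as.integer(sum(kids == 2L))
}

# Leaf set below each node, as a list indexed by node number.
.node_tipsets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  sets <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Nontrivial bipartitions of a tree
#'
#' The splits of the leaf set induced by the internal edges of the
#' unrooted tree; trivial splits (one leaf against the rest) are excluded.
#' A fully resolved tree on n leaves has exactly n - 3 of them; a star
#' tree has none. The set is invariant under re-rooting.
#'
#' @param tree A `phylo` object with at least 4 leaves.
#' @return A named list of class `"bipartition_set"`: one element per
#'   nontrivial split, each a sorted character vector holding the side of
#'   the split that does not contain the alphabetically first leaf; names
#'   are canonical orientation-independent keys. Attribute `"taxa"` holds
#'   the full leaf set.
#' @export
nontrivial_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 4L) stop("need at least 4 leaves")
  ut <- ape::unroot(tree)
  taxa <- ut$tip.label
  n_tip <- ape::Ntip(ut)
  sets <- .node_tipsets(ut)
  root <- n_tip + 1L
  out <- list()
  for (k in seq_len(nrow(ut$edge))) {
    ch <- ut$edge[k, 2L]
    if (ch <= n_tip) next                    # trivial by construction
    clade <- sets[[ch]]
    if (length(clade) < 2L || length(clade) > n_tip - 2L) next
    key <- split_key(clade, taxa)
    side <- if (min(taxa) %in% clade) setdiff(taxa, clade) else clade
    out[[key]] <- sort(side)
  }
  structure(out, taxa = sort(taxa), class = "bipartition_set")
}

#' @export
print.bipartition_set <- function(x, ...) {
  cat("Bipartition set:", length(x), "nontrivial split(s) on",
      length(attr(x, "taxa")), "leaves\n")
  for (s in x) cat("  ", paste(s, collapse = " "), "| rest\n")
  invisible(x)
}
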