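# Synthetic-data generator: random trees, partitioned GTR+I+G sequence
# evolution, a distance-based tree estimator for recovery experiments,
# and controlled-concordance gene-tree fixtures. The defaults mirror the
# structure of a genus-level mitogenome study: 51 taxa and 15 gene
# partitions with realistic mitochondrial gene lengths.

#' Default mitochondrial partition lengths
#'
#' The 13 protein-coding genes plus the two rRNAs of a vertebrate
#' mitogenome, with typical alignment lengths in bp (168 bp ATP8 up to
#' 1,840 bp ND5; rRNAs 958 and 1,653 bp; 14,029 bp in total).
#'
#' @return `data.frame` with columns `gene`, `length`.
#' @export
default_partition_lengths <- function() {
  data.frame(
    gene = c("ND1", "ND2", "ND3", "ND4", "ND4l", "ND5", "ND6",
             "ATP6", "ATP8", "COI", "COII", "COIII", "CytB",
             "16S", "12S"),
    length = c(966L, 1059L, 351L, 1362L, 289L, 1840L, 534L,
               690L, 168L, 1549L, 684L, 785L, 1141L,
               1653L, 958L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' genus-level mitogenome study: 51 taxa, a Yule tree scaled to a maximum
#' root-to-tip height of 0.3 substitutions/site (congeneric mitochondrial
#' divergence), the 15 mitochondrial partitions of
#' [default_partition_lengths()], and a transition-biased GTR+I+G model
#' with mtDNA-like base composition.
#'
#' @param n_taxa Number of leaves (default 51; at least 4).
#' @param tree_model `"yule"` or `"birth-death"`.
#' @param birth,death Speciation/extinction rates per lineage per unit
#'   time (`death` forced to 0 under `"yule"`).
#' @param tree_height Maximum root-to-tip path length after rescaling, in
#'   substitutions/site; `NULL` keeps the raw birth-death depth.
#' @param partitions `data.frame` with `gene`, `length` (bp).
#' @param model A [substitution_model()] shared by all partitions.
#' @param rate_multipliers Per-partition rate multipliers (named or in
#'   partition order; default all 1).
#' @param seed Mandatory integer seed; every stochastic operation derives
#'   its stream from it.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_taxa = 51L,
                              tree_model = c("yule", "birth-death"),
                              birth = 1, death = 0, tree_height = 0.3,
                              partitions = default_partition_lengths(),
                              model = substitution_model(
                                rates = c(1, 6, 1, 1, 6, 1),
                                base_freqs = c(0.33, 0.28, 0.12, 0.27),
                                p_invariant = 0.3, gamma_shape = 0.5),
                              rate_multipliers = NULL,
                              seed) {
  tree_model <- match.arg(tree_model)
  if (missing(seed)) stop("`seed` is required")
  stopifnot(n_taxa >= 4L, birth > 0, death >= 0,
            is.data.frame(partitions),
            all(c("gene", "length") %in% names(partitions)),
            all(partitions$length > 0),
            !anyDuplicated(partitions$gene))
  if (tree_model == "yule") death <- 0
  if (is.null(rate_multipliers))
    rate_multipliers <- stats::setNames(rep(1, nrow(partitions)),
                                        partitions$gene)
  if (is.null(names(rate_multipliers)))
    names(rate_multipliers) <- partitions$gene
  stopifnot(setequal(names(rate_multipliers), partitions$gene),
            all(rate_multipliers > 0))
  structure(list(n_taxa = as.integer(n_taxa), tree_model = tree_model,
                 birth = birth, death = death, tree_height = tree_height,
                 partitions = partitions, model = model,
                 rate_multipliers = rate_multipliers,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:", x$n_taxa, "taxa,", nrow(x$partitions),
      "partition(s),", sum(x$partitions$length), "bp total;",
      x$tree_model, "tree", if (!is.null(x$tree_height))
        paste0("(height ", x$tree_height, ")"), "; seed", x$seed, "\n")
  invisible(x)
}

#' Simulate a random resolved tree
#'
#' Birth-death (or pure-birth Yule) tree on `n_taxa` leaves via
#' [ape::rphylo()], optionally rescaled so the maximum root-to-tip path
#' equals `tree_height`. Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @param seed Override seed (defaults to `config$seed`).
#' @return Rooted, fully bifurcating `phylo` with leaves `t1..tN`.
#' @export
simulate_tree <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    tree <- ape::rphylo(config$n_taxa, config$birth, config$death)
    if (!is.null(config$tree_height)) {
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length * config$tree_height / depth
    }
    tree
  })
}

#' Evolve a partitioned alignment along a tree
#'
#' Root states are drawn from the model's base frequencies and evolved
#' edge-wise with matrix-exponential transition probabilities. Each site
#' is invariant with probability `p_invariant`, otherwise it draws a
#' discrete gamma category; each partition additionally applies its own
#' rate multiplier. The returned alignment carries the partition map.
#'
#' @param tree `phylo` with branch lengths.
#' @param config A [simulation_config()].
#' @param seed Override seed (defaults to `config$seed + 1`).
#' @return A [dna_alignment()] with `$partitions` set.
#' @export
evolve_alignment <- function(tree, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  model <- config$model
  classes <- rate_classes(model)
  n_tip <- ape::Ntip(tree)
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre_len <- ape::reorder.phylo(tree, "postorder")$edge.length
  ord <- rev(seq_len(nrow(pre)))   # preorder: parents before children
  pre <- pre[ord, , drop = FALSE]; pre_len <- pre_len[ord]
  root <- n_tip + 1L
  with_seed(seed, {
    blocks <- vector("list", nrow(config$partitions))
    for (g in seq_len(nrow(config$partitions))) {
      L <- config$partitions$length[g]
      mult <- config$rate_multipliers[[config$partitions$gene[g]]]
      cls <- sample.int(nrow(classes), L, replace = TRUE,
                        prob = classes$weight)
      site_rate <- classes$rate[cls] * mult
      states <- vector("list", n_tip + tree$Nnode)
      states[[root]] <- sample.int(4L, L, replace = TRUE,
                                   prob = model$base_freqs)
      for (k in seq_len(nrow(pre))) {
        p <- pre[k, 1L]; ch <- pre[k, 2L]; t <- pre_len[k]
        parent_state <- states[[p]]
        child <- integer(L)
        for (rv in unique(site_rate)) {
          idx <- which(site_rate == rv)
          if (rv == 0 || t == 0) { child[idx] <- parent_state[idx]; next }
          P <- transition_probability(model, t * rv)
          for (x in 1:4) {
            ii <- idx[parent_state[idx] == x]
            if (length(ii))
              child[ii] <- sample.int(4L, length(ii), replace = TRUE,
                                      prob = P[x, ])
          }
        }
        states[[ch]] <- child
      }
      tipm <- do.call(rbind, states[seq_len(n_tip)])
      blocks[[g]] <- matrix(.BASES[tipm], nrow = n_tip)
    }
    m <- do.call(cbind, blocks)
    rownames(m) <- tree$tip.label
    ends <- cumsum(config$partitions$length)
    dna_alignment(m, partitions = data.frame(
      gene = config$partitions$gene,
      start = c(1L, utils::head(ends, -1L) + 1L),
      end = ends, stringsAsFactors = FALSE))
  })
}

#' Distance-based tree estimate
#'
#' Model-corrected distances followed by [neighbor_joining()]: a simple,
#' fully reproducible estimator for simulation recovery experiments (it
#' does not replace likelihood or Bayesian inference on real data).
#'
#' @param aln A [dna_alignment()] with at least 4 taxa.
#' @param model Distance correction model (see
#'   [corrected_distance_matrix()]).
#' @return Unrooted `phylo`.
#' @export
estimate_tree_nj <- function(aln, model = "JC69") {
  stopifnot(nrow(aln$seq) >= 4L)
  d <- corrected_distance_matrix(aln, model = model)
  if (anyNA(d))
    stop(attr(d, "n_undefined"),
         " taxon pair(s) have no defined corrected distance; cannot build NJ tree")
  neighbor_joining(d)
}

#' Canonical key of the branch separating a clade
#'
#' @param tree `phylo`.
#' @param clade Character vector of tip labels on one side of the branch.
#' @return The canonical split key used by the concordance functions.
#' @export
branch_key <- function(tree, clade) {
  stopifnot(all(clade %in% tree$tip.label))
  key <- split_key(clade, sort(tree$tip.label))
  if (!key %in% names(nontrivial_bipartitions(tree)))
    stop("not a nontrivial branch of the tree: {",
         paste(sort(clade), collapse = ", "), "}")
  key
}

#' One nearest-neighbour-interchange rearrangement
#'
#' Swaps two subtrees across an internal edge, producing a topology at
#' the minimum nonzero RF distance from the input. Deterministic: the
#' `edge`-th eligible internal edge is rearranged.
#'
#' @param tree Resolved `phylo` (at least 4 leaves).
#' @param edge Index among eligible internal edges (default 1).
#' @return Rearranged `phylo`.
#' @export
nni_neighbor <- function(tree, edge = 1L) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 4L)
  tree <- ape::unroot(tree)  # an NNI across a root-incident edge is a no-op
  n_tip <- ape::Ntip(tree)
  internal <- which(tree$edge[, 2L] > n_tip)
  if (edge > length(internal)) stop("only ", length(internal),
                                    " eligible internal edges")
  k <- internal[edge]
  p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
  kids_ch <- which(tree$edge[, 1L] == ch)
  kids_p <- setdiff(which(tree$edge[, 1L] == p), k)
  if (!length(kids_p) || length(kids_ch) < 2L)
    stop("edge not eligible for NNI")
  # swap one child of `ch` with one sibling of `ch`
  e <- tree$edge
  e[kids_p[1L], 1L] <- ch
  e[kids_ch[1L], 1L] <- p
  tree$edge <- e
  ape::read.tree(text = ape::write.tree(tree))
}

#' Gene-tree set with prescribed branch concordance
#'
#' Builds `n_trees` gene trees from a resolved reference such that each
#' designated branch appears in exactly `round(fraction * n_trees)` of
#' them: in the remaining trees the branch is collapsed and the resulting
#' polytomy randomly re-resolved (re-drawn if the resolution recreates
#' the branch; left as a polytomy after 100 rejections). All other
#' reference branches are preserved, so [gene_concordance_factor()] on
#' the output recovers the requested percentages exactly.
#'
#' @param reference Resolved `phylo`.
#' @param per_branch_support Named numeric vector of fractions in
#'   \[0, 1\]; names are canonical branch keys (see [branch_key()]).
#' @param n_trees Number of gene trees.
#' @param seed Integer seed.
#' @return Named list of `phylo` objects (`gene1..geneN`).
#' @export
make_concordance_fixture <- function(reference, per_branch_support,
                                     n_trees, seed) {
  stopifnot(inherits(reference, "phylo"), n_trees >= 1L)
  if (!ape::is.binary(reference)) stop("reference must be fully resolved")
  if (any(per_branch_support < 0 | per_branch_support > 1))
    stop("fractions must lie in [0, 1]")
  splits <- nontrivial_bipartitions(reference)
  unknown <- setdiff(names(per_branch_support), names(splits))
  if (length(unknown))
    stop("not a nontrivial branch of the reference: ",
         paste(unknown, collapse = "; "))
  # unroot first: a root-adjacent branch is represented by two rooted
  # edges, and collapsing only one of them would leave the split intact
  ref <- ape::unroot(reference)
  ref$edge.length <- rep(1, nrow(ref$edge))
  ref$node.label <- NULL
  n_tip <- ape::Ntip(ref)
  taxa <- sort(ref$tip.label)
  sets <- .node_tipsets(ref)
  edge_of_key <- vapply(names(per_branch_support), function(key) {
    for (k in seq_len(nrow(ref$edge))) {
      chn <- ref$edge[k, 2L]
      if (chn <= n_tip) next
      clade <- sets[[chn]]
      if (length(clade) < 2L || length(clade) > n_tip - 2L) next
      if (split_key(clade, taxa) == key) return(k)
    }
    NA_integer_
  }, integer(1L))
  if (anyNA(edge_of_key)) stop("branch key not found on an internal edge")
  n_present <- round(per_branch_support * n_trees)
  with_seed(seed, {
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      absent <- names(per_branch_support)[i > n_present]
      if (!length(absent)) { trees[[i]] <- ref; next }
      t0 <- ref
      t0$edge.length[edge_of_key[absent]] <- 0
      collapsed <- ape::di2multi(t0, tol = 1e-9)
      for (try in seq_len(100L)) {
        res <- ape::multi2di(collapsed, random = TRUE)
        keys <- names(nontrivial_bipartitions(res))
        if (!any(absent %in% keys)) break
        res <- NULL
      }
      trees[[i]] <- if (is.null(res)) collapsed else res
    }
    names(trees) <- paste0("gene", seq_len(n_trees))
    trees
  })
}

#' Write a complete simulated study to disk
#'
#' Simulates a reference tree and a partitioned alignment, estimates one
#' NJ gene tree per partition, and writes everything in the pipeline's
#' input formats: `reference.nwk`, `alignment.fasta`, `partitions.txt`,
#' one `genes/<gene>.fasta` and `genes/<gene>.nwk` per partition, and a
#' ready-to-run `config.yaml`.
#'
#' @param dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @return Invisibly, a list with the true tree, the alignment, the gene
#'   trees and the config path.
#' @export
write_simulated_study <- function(dir, config) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  tree <- simulate_tree(config)
  aln <- evolve_alignment(tree, config)
  write_newick(tree, file.path(dir, "reference.nwk"))
  write_fasta_alignment(aln, file.path(dir, "alignment.fasta"))
  write_partition_file(aln$partitions, file.path(dir, "partitions.txt"))
  gene_trees <- list()
  genes_cfg <- list()
  for (g in aln$partitions$gene) {
    sub <- extract_partition(aln, g)
    gt <- estimate_tree_nj(sub)
    gene_trees[[g]] <- gt
    write_fasta_alignment(sub, file.path(dir, "genes", paste0(g, ".fasta")))
    write_newick(gt, file.path(dir, "genes", paste0(g, ".nwk")))
    genes_cfg[[g]] <- list(tree = file.path("genes", paste0(g, ".nwk")),
                           alignment = file.path("genes", paste0(g, ".fasta")))
  }
  cfg <- list(reference_tree = "reference.nwk",
              reference_alignment = "alignment.fasta",
              genes = genes_cfg,
              seed = config$seed,
              sh_replicates = 1000L,
              scf_quartets = 100L,
              correction_model = "JC69",
              output_dir = "results")
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(tree = tree, alignment = aln, gene_trees = gene_trees,
                 config_path = file.path(dir, "config.yaml")))
}
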