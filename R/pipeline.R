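# Orchestration: assemble the per-partition congruence summary table,
# the ANOVA explaining RF distance, and the full pipeline run with its
# file outputs (summary, RF matrix + dendrogram, concordance-annotated
# reference, scatter data, SH table, ANOVA table, log).

#' Per-partition congruence summary
#'
#' One row per gene/partition plus one for the reference: polytomy
#' branches, saturation slope, mean node support, fully bifurcating
#' nodes, alignment length, parsimony-informative sites, SIC, RF distance
#' from the reference, and (optionally) the SH test p-value of each
#' topology against the reference alignment. Per-gene failures (e.g. a
#' saturation regression with too many undefined pairs) leave that cell
#' `NA` and are collected in the `"notes"` attribute; the table is still
#' emitted.
#'
#' @param reference `phylo` reference tree.
#' @param genes Named list; each element a list with components `tree`
#'   (`phylo`) and `alignment` ([dna_alignment()]).
#' @param reference_alignment Optional alignment for the reference row
#'   (typically the concatenation); also the default SH test alignment.
#' @param model Optional [substitution_model()] for the SH test; `NULL`
#'   fits heuristics via [estimate_model()].
#' @param sh_replicates RELL replicates; 0 skips the SH column.
#' @param correction_model Distance correction for the saturation column.
#' @param seed Integer seed (drives the SH resampling).
#' @param reference_name Row label for the reference (default
#'   `"reference"`).
#' @return `data.frame` with the columns above, reference row first.
#' @export
build_summary <- function(reference, genes, reference_alignment = NULL,
                          model = NULL, sh_replicates = 1000L,
                          correction_model = "JC69", seed = 1L,
                          reference_name = "reference") {
  stopifnot(inherits(reference, "phylo"), is.list(genes), length(genes) >= 1L)
  if (is.null(names(genes))) stop("`genes` must be named")
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))

  metrics_row <- function(id, tree, aln, rf) {
    slope <- tryCatch(
      saturation_regression(aln, model = correction_model)$slope,
      error = function(e) { note(id, ": saturation skipped (",
                                 conditionMessage(e), ")"); NA_real_ })
    support <- tryCatch(mean_node_support(tree),
      error = function(e) { note(id, ": no node supports"); NA_real_ })
    len <- alignment_length(aln)
    pi_sites <- count_parsimony_informative(aln)
    data.frame(partition_id = id,
               polytomy_branches = count_polytomy_branches(tree),
               saturation_slope = slope,
               mean_node_support = support,
               bifurcating_nodes = count_bifurcating_nodes(tree),
               alignment_length_bp = len,
               pi_sites = pi_sites,
               sic = sic_value(pi_sites, len),
               rf_from_reference = rf,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  if (!is.null(reference_alignment))
    rows[[reference_name]] <- metrics_row(reference_name, reference,
                                          reference_alignment, 0L)
  for (g in names(genes)) {
    rows[[g]] <- tryCatch(
      metrics_row(g, genes[[g]]$tree, genes[[g]]$alignment,
                  rf_distance(genes[[g]]$tree, reference)),
      error = function(e) {
        note(g, ": row failed (", conditionMessage(e), ")")
        data.frame(partition_id = g, polytomy_branches = NA_integer_,
                   saturation_slope = NA_real_, mean_node_support = NA_real_,
                   bifurcating_nodes = NA_integer_,
                   alignment_length_bp = NA_integer_, pi_sites = NA_integer_,
                   sic = NA_real_, rf_from_reference = NA_integer_,
                   stringsAsFactors = FALSE)
      })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  out$sh_p_value <- NA_real_
  if (sh_replicates > 0L) {
    sh_aln <- reference_alignment
    if (is.null(sh_aln)) {
      note("SH test skipped: no reference alignment supplied")
    } else {
      trees <- c(stats::setNames(list(reference), reference_name),
                 lapply(genes, `[[`, "tree"))
      if (is.null(model)) model <- estimate_model(sh_aln, .with_lengths(reference))
      sh <- sh_test(sh_aln, lapply(trees, .with_lengths), model,
                    n_replicates = sh_replicates, seed = seed)
      out$sh_p_value <- sh$p_value[match(out$partition_id, sh$tree_id)]
    }
  }
  attr(out, "notes") <- notes
  out
}

# likelihood ops need branch lengths; give length-less topologies a start
.with_lengths <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    tree$edge.length <- rep(0.05, nrow(tree$edge))
  tree
}

#' Sequential ANOVA explaining RF distance
#'
#' Ordinary-least-squares fit of the RF distance from the reference on an
#' ordered list of terms, with sequential (Type-I) F tests, so the term
#' order matters and is part of the model specification. Default terms:
#' saturation slope, alignment length, and the length-by-informative-sites
#' interaction. Topology-derived metrics (polytomies, bifurcating nodes,
#' mean support) are deliberately not offered as default terms because
#' they are intrinsically linked to the response. The reference row
#' (RF = 0 by construction) is excluded.
#'
#' @param summary Output of [build_summary()].
#' @param terms Character vector of model terms, in testing order; `:`
#'   denotes an interaction.
#' @param reference_name Row to exclude.
#' @return `data.frame` of class `"rf_anova"`: one row per term plus
#'   `Residuals`, with `df`, `sum_sq`, `mean_sq`, `f_value`, `p_value`.
#' @export
explain_rf_anova <- function(summary,
                             terms = c("saturation_slope",
                                       "alignment_length_bp",
                                       "alignment_length_bp:pi_sites"),
                             reference_name = "reference") {
  d <- summary[summary$partition_id != reference_name, , drop = FALSE]
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  d <- d[stats::complete.cases(d[, c("rf_from_reference", vars)]), ,
         drop = FALSE]
  if (nrow(d) < length(terms) + 2L)
    stop("need at least ", length(terms) + 2L, " complete rows, have ", nrow(d))
  for (v in vars)
    if (stats::var(d[[v]]) == 0)
      stop("constant predictor: ", v)
  f <- stats::as.formula(paste("rf_from_reference ~",
                               paste(terms, collapse = " + ")))
  fit <- stats::aov(f, data = d)
  a <- stats::anova(fit)
  out <- data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                    mean_sq = a$`Mean Sq`, f_value = a$`F value`,
                    p_value = a$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rf_anova", class(out))
  out
}

.read_gene_inputs <- function(cfg, base) {
  path <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  problems <- character(0)
  must <- function(p, what) {
    fp <- path(p)
    if (!file.exists(fp)) problems <<- c(problems, paste0("missing ", what, ": ", fp))
    fp
  }
  ref_path <- must(cfg$reference_tree, "reference tree")
  ref_aln_path <- if (!is.null(cfg$reference_alignment))
    must(cfg$reference_alignment, "reference alignment") else NULL
  gene_paths <- lapply(names(cfg$genes), function(g) {
    list(tree = must(cfg$genes[[g]]$tree, paste0("tree for ", g)),
         alignment = must(cfg$genes[[g]]$alignment, paste0("alignment for ", g)))
  })
  names(gene_paths) <- names(cfg$genes)
  if (length(problems)) stop("configuration problems:\n  ",
                             paste(problems, collapse = "\n  "))
  genes <- lapply(gene_paths, function(p)
    list(tree = read_newick(file = p$tree),
         alignment = read_fasta_alignment(p$alignment)))
  list(reference = read_newick(file = ref_path),
       reference_alignment = if (!is.null(ref_aln_path))
         read_fasta_alignment(ref_aln_path) else NULL,
       genes = genes)
}

#' Run the full congruence pipeline
#'
#' Reads a YAML config (reference tree, per-gene trees and alignments,
#' seed, test settings), validates every input up front, and writes the
#' study deliverables to the output directory: `summary.csv` (the
#' per-partition metrics table), `rf_matrix.csv` / `rf_matrix.phy`,
#' `dendrogram.nwk` (NJ on the RF matrix), `concordance.csv` and
#' `reference_annotated.nwk` (gCF/sCF), `length_vs_rf.csv`,
#' `saturation/<gene>.csv` scatter data, `sh_test.csv`, `anova.csv`, and
#' `run.log`. Reruns with the same config and seed are byte-identical.
#'
#' @param config_path Path to the YAML config (see the packaged demo
#'   written by [write_simulated_study()] for the schema).
#' @param output_dir Override for the config's `output_dir`.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config_path, output_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  if (is.null(cfg$seed)) stop("config must set a seed")
  inputs <- .read_gene_inputs(cfg, base)
  out <- output_dir %||% cfg$output_dir %||% "results"
  if (!grepl("^/", out)) out <- file.path(base, out)
  dir.create(file.path(out, "saturation"), recursive = TRUE,
             showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("mitoconcord ", as.character(utils::packageVersion("mitoconcord")),
          " | ", R.version.string)
  logline("config: ", normalizePath(config_path), " | seed: ", seed)
  logline("genes: ", paste(names(inputs$genes), collapse = ", "))

  corr <- cfg$correction_model %||% "JC69"
  summary <- build_summary(
    inputs$reference, inputs$genes,
    reference_alignment = inputs$reference_alignment,
    sh_replicates = cfg$sh_replicates %||% 1000L,
    correction_model = corr, seed = seed)
  for (n in attr(summary, "notes")) logline("note: ", n)
  .write_csv(summary, file.path(out, "summary.csv"))

  trees <- c(list(reference = inputs$reference),
             lapply(inputs$genes, `[[`, "tree"))
  rfm <- rf_matrix(trees)
  .write_csv(data.frame(tree = rownames(rfm), rfm, check.names = FALSE),
             file.path(out, "rf_matrix.csv"))
  write_phylip_matrix(rfm, file.path(out, "rf_matrix.phy"))
  dendro <- neighbor_joining(rfm)
  if (attr(dendro, "clamped_deficit") > 0)
    logline("dendrogram: clamped negative branch lengths, total deficit ",
            signif(attr(dendro, "clamped_deficit"), 4))
  write_newick(dendro, file.path(out, "dendrogram.nwk"))

  gcf <- gene_concordance_factor(inputs$reference,
                                 lapply(inputs$genes, `[[`, "tree"))
  scf <- NULL
  if (!is.null(inputs$reference_alignment)) {
    scf <- site_concordance_factor(inputs$reference,
                                   inputs$reference_alignment,
                                   n_quartets = cfg$scf_quartets %||% 100L,
                                   seed = seed + 1L)
    conc <- merge(gcf, scf[, c("branch", "scf", "n_quartets_sampled",
                               "n_quartets_decisive")],
                  by = "branch", all.x = TRUE, sort = FALSE)
  } else conc <- gcf
  .write_csv(conc, file.path(out, "concordance.csv"))
  write_newick(annotate_concordance(inputs$reference, gcf, scf),
               file.path(out, "reference_annotated.nwk"))

  .write_csv(summary[summary$partition_id != "reference",
                     c("partition_id", "alignment_length_bp",
                       "rf_from_reference")],
             file.path(out, "length_vs_rf.csv"))

  for (g in names(inputs$genes)) {
    sc <- tryCatch(saturation_scatter(inputs$genes[[g]]$alignment,
                                      model = corr),
                   error = function(e) NULL)
    if (!is.null(sc))
      .write_csv(sc, file.path(out, "saturation", paste0(g, ".csv")))
  }

  .write_csv(summary[, c("partition_id", "sh_p_value")],
             file.path(out, "sh_test.csv"))

  anova_tab <- tryCatch(explain_rf_anova(summary), error = function(e) {
    logline("anova skipped: ", conditionMessage(e)); NULL })
  if (!is.null(anova_tab)) .write_csv(anova_tab, file.path(out, "anova.csv"))
  logline("done: ", length(list.files(out, recursive = TRUE)),
          " output file(s)")
  invisible(out)
}

.write_csv <- function(d, path) {
  utils::write.csv(format(d, trim = TRUE, digits = 10, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
}
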