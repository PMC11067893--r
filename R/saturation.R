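#' Substitution-saturation regression
#'
#' Regresses uncorrected p-distances (response) on model-corrected
#' distances (predictor) over all taxon pairs with a defined correction,
#' by ordinary least squares with a free intercept. Because corrections
#' are convex (corrected >= observed), the slope is at most ~1; the lower
#' the slope, the more multiple hits the observed distances are hiding,
#' i.e. the more saturated the gene.
#'
#' Pairs whose corrected distance is undefined (observed divergence at or
#' beyond the model's bound, or no comparable sites) are excluded and
#' counted. When more than `max_excluded_frac` of the pairs are excluded
#' the regression is considered unreliable for that gene and an error is
#' raised; callers assembling summary tables catch this and report the
#' slope as missing.
#'
#' @param aln A [dna_alignment()] with at least 3 taxa.
#' @param model Correction model, see [corrected_distance_matrix()].
#' @param max_excluded_frac Maximum tolerated fraction of excluded pairs
#'   (default 0.25).
#' @return A list of class `"saturation_result"`: `slope`, `intercept`,
#'   `r_squared`, `n_pairs`, `n_excluded_pairs`, `model`.
#' @export
saturation_regression <- function(aln, model = "JC69",
                                  max_excluded_frac = 0.25) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (nrow(aln$seq) < 3L) stop("need at least 3 taxa")
  p <- p_distance_matrix(aln)
  d <- corrected_distance_matrix(aln, model = model)
  lower <- lower.tri(p)
  x <- d[lower]; y <- p[lower]
  keep <- is.finite(x) & is.finite(y)
  n_total <- sum(lower)
  n_excl <- n_total - sum(keep)
  if (n_excl / n_total > max_excluded_frac)
    stop(sprintf("saturation regression unreliable: %d of %d pairs have no defined corrected distance",
                 n_excl, n_total))
  if (sum(keep) < 3L) stop("fewer than 3 defined pairs")
  x <- x[keep]; y <- y[keep]
  if (stats::var(x) == 0)
    stop("zero variance in corrected distances (e.g. all sequences identical)")
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 n_pairs = sum(keep),
                 n_excluded_pairs = n_excl,
                 model = attr(d, "model")),
            class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("Saturation regression (%s): slope %.3f, intercept %.4f, R2 %.3f (%d pairs, %d excluded)\n",
              x$model, x$slope, x$intercept, x$r_squared,
              x$n_pairs, x$n_excluded_pairs))
  invisible(x)
}

#' Per-pair saturation scatter data
#'
#' The (corrected, uncorrected) distance pairs behind
#' [saturation_regression()], for plotting or export.
#'
#' @inheritParams saturation_regression
#' @return `data.frame` with columns `taxon_a`, `taxon_b`,
#'   `corrected_dist`, `p_dist` (undefined pairs included as `NA`).
#' @export
saturation_scatter <- function(aln, model = "JC69") {
  p <- p_distance_matrix(aln)
  d <- corrected_distance_matrix(aln, model = model)
  idx <- which(lower.tri(p), arr.ind = TRUE)
  data.frame(taxon_a = rownames(p)[idx[, 1L]],
             taxon_b = colnames(p)[idx[, 2L]],
             corrected_dist = d[idx],
             p_dist = p[idx],
             stringsAsFactors = FALSE)
}
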