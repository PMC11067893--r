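# Pairwise sequence distances: uncorrected p-distances and closed-form
# model corrections (JC69, K80, TN93). Only unambiguous bases are
# compared; every pair uses its own overlap (pairwise deletion), the
# right convention for gap-rich rRNA alignments.

.BASES <- c("A", "C", "G", "T")

# integer-coded matrix: 1..4 = ACGT, NA = gap/ambiguity
.base_codes <- function(aln) {
  m <- matrix(match(aln$seq, .BASES), nrow = nrow(aln$seq),
              dimnames = dimnames(aln$seq))
  m
}

#' Uncorrected pairwise p-distances
#'
#' Proportion of differing sites among the columns where both sequences
#' carry unambiguous bases (pairwise deletion). A pair with no comparable
#' site gets `NA`, never 0.
#'
#' @param aln A [dna_alignment()] with at least 2 taxa.
#' @return Symmetric matrix with zero diagonal; attribute
#'   `"n_comparable"` holds the per-pair overlap counts.
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"), nrow(aln$seq) >= 2L)
  code <- .base_codes(aln)
  n <- nrow(code)
  d <- matrix(0, n, n, dimnames = list(rownames(code), rownames(code)))
  nc <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(code[i, ]) & !is.na(code[j, ])
    m <- sum(ok)
    nc[i, j] <- nc[j, i] <- m
    d[i, j] <- d[j, i] <- if (m == 0L) NA_real_ else
      sum(code[i, ok] != code[j, ok]) / m
  }
  attr(d, "n_comparable") <- nc
  d
}

# per-pair substitution-type proportions over comparable sites
.pair_props <- function(ci, cj) {
  ok <- !is.na(ci) & !is.na(cj)
  m <- sum(ok)
  if (m == 0L) return(NULL)
  a <- ci[ok]; b <- cj[ok]
  diff <- a != b
  # transitions: A<->G (1,3), C<->T (2,4)
  ag <- sum(diff & ((a == 1L & b == 3L) | (a == 3L & b == 1L)))
  ct <- sum(diff & ((a == 2L & b == 4L) | (a == 4L & b == 2L)))
  list(n = m, p = sum(diff) / m, P1 = ag / m, P2 = ct / m,
       Q = (sum(diff) - ag - ct) / m)
}

#' Model-corrected pairwise distances
#'
#' Closed-form corrected distances under JC69, K80 or TN93. Pairs whose
#' observed divergence is at or beyond the model's saturation bound (for
#' JC69, p >= 0.75) have no defined correction and are returned as `NA`;
#' the number of such pairs is recorded in the `"n_undefined"` attribute.
#' TN93 uses base frequencies pooled over the whole alignment.
#'
#' @param aln A [dna_alignment()].
#' @param model `"JC69"`, `"K80"` or `"TN93"`.
#' @return Symmetric matrix with zero diagonal and `NA` for undefined
#'   pairs; attributes `"model"` and `"n_undefined"`.
#' @export
corrected_distance_matrix <- function(aln, model = c("JC69", "K80", "TN93")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "dna_alignment"), nrow(aln$seq) >= 2L)
  code <- .base_codes(aln)
  n <- nrow(code)
  d <- matrix(0, n, n, dimnames = list(rownames(code), rownames(code)))
  if (model == "TN93") {
    f <- tabulate(code, nbins = 4L)
    if (!sum(f)) stop("alignment has no unambiguous bases")
    bf <- f / sum(f)
  }
  n_undef <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pr <- .pair_props(code[i, ], code[j, ])
    v <- if (is.null(pr)) NA_real_ else switch(model,
      JC69 = {
        if (pr$p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * pr$p / 3)
      },
      K80 = {
        P <- pr$P1 + pr$P2; Q <- pr$Q
        w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
        if (w1 <= 0 || w2 <= 0) NA_real_ else
          -0.5 * log(w1) - 0.25 * log(w2)
      },
      TN93 = {
        gR <- bf[1L] + bf[3L]; gY <- bf[2L] + bf[4L]
        k1 <- 2 * bf[1L] * bf[3L] / gR
        k2 <- 2 * bf[2L] * bf[4L] / gY
        k3 <- 2 * (gR * gY - bf[1L] * bf[3L] * gY / gR -
                     bf[2L] * bf[4L] * gR / gY)
        w1 <- 1 - pr$P1 / k1 - pr$Q / (2 * gR)
        w2 <- 1 - pr$P2 / k2 - pr$Q / (2 * gY)
        w3 <- 1 - pr$Q / (2 * gR * gY)
        if (w1 <= 0 || w2 <= 0 || w3 <= 0) NA_real_ else
          -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
      })
    if (is.na(v) && !is.null(pr)) n_undef <- n_undef + 1L
    if (is.null(pr)) v <- NA_real_
    d[i, j] <- d[j, i] <- v
  }
  attr(d, "model") <- model
  attr(d, "n_undefined") <- n_undef
  d
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param d Symmetric matrix with row/column names.
#' @param path Output file.
#' @export
write_phylip_matrix <- function(d, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10L),
                     paste(formatC(d[i, ], format = "g", digits = 6L),
                           collapse = "  ")), con)
  invisible(path)
}
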