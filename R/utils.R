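# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's stream.
# seed = NULL means "use the current stream as-is".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical orientation-independent key for a leaf-set split.
# `side` is one side of the split; `taxa` the full leaf set.
# The key lists, sorted, the side that does NOT contain the
# alphabetically first taxon, so both orientations hash identically.
split_key <- function(side, taxa) {
  anchor <- min(taxa)
  if (anchor %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = "\r")
}
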