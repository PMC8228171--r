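# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Leaves the caller's RNG stream untouched; seed = NULL uses the current
# stream (and does advance it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locale-independent ordering of intervals by (chrom, start, end).
interval_order <- function(chrom, start, end) {
  order(chrom, start, end, method = "radix")
}

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
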