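#' Randomly re-place intervals on a genome
#'
#' Each interval keeps its length and is independently placed uniformly among
#' all genome-wide positions where it fits wholly on one chromosome
#' (equivalently: chromosome chosen with probability proportional to its
#' number of eligible start positions). Shuffled intervals may overlap each
#' other, and no region is excluded — the behaviour of the standard
#' interval-shuffling tools with default options.
#'
#' @param a Interval data.frame.
#' @param layout Genome layout.
#' @param seed Integer seed (NULL = current RNG stream).
#' @param per_chrom Keep each interval on its own chromosome instead of
#'   placing genome-wide. Default FALSE.
#' @return Interval data.frame of the same lengths, newly placed.
#' @export
shuffle_intervals <- function(a, layout, seed = NULL, per_chrom = FALSE) {
  validate_intervals(a, "A")
  if (nrow(a) == 0L) return(a[, c("chrom", "start", "end")])
  len <- a$end - a$start
  if (any(len > max(layout$length)))
    stop("interval longer than every chromosome")
  with_seed(seed, {
    chrom <- character(nrow(a)); start <- numeric(nrow(a))
    for (i in seq_len(nrow(a))) {
      if (per_chrom) {
        ch <- a$chrom[i]
        elig <- chrom_length(layout, ch) - len[i] + 1
        if (elig < 1) stop("interval does not fit on its chromosome: ", ch)
      } else {
        elig_all <- pmax(layout$length - len[i] + 1, 0)
        ch <- sample(layout$chrom, 1L, prob = elig_all)
        elig <- elig_all[match(ch, layout$chrom)]
      }
      chrom[i] <- ch
      start[i] <- floor(stats::runif(1, 0, elig))
    }
    data.frame(chrom = chrom, start = start, end = start + len,
               stringsAsFactors = FALSE)
  })
}

#' Permutation test for interval-set overlap
#'
#' Tests whether the number of intervals of `a` intersecting the annotation
#' `b` exceeds what random placement would produce. The statistic is a count
#' of A-intervals hit (not overlapping bp). The null is built by re-placing
#' `a` with [shuffle_intervals()] `n_perm` times; the empirical p-value uses
#' the add-one estimator `(1 + #{null >= observed}) / (1 + n_perm)`, so it is
#' never exactly zero.
#'
#' @param a,b Interval data.frames (query set and annotation).
#' @param layout Genome layout.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param per_chrom Passed to [shuffle_intervals()].
#' @return Object of class `permutation_result`: `observed_count`,
#'   `null_counts`, `null_mean`, `null_min`, `null_max`, `empirical_p`.
#' @export
permutation_test <- function(a, b, layout, n_perm = 1000, seed = NULL,
                             per_chrom = FALSE) {
  stopifnot(n_perm >= 1)
  observed <- count_intersecting(a, b)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      count_intersecting(shuffle_intervals(a, layout, per_chrom = per_chrom),
                         b),
      0L)
  })
  structure(list(observed_count = observed,
                 null_counts = null_counts,
                 null_mean = mean(null_counts),
                 null_min = min(null_counts),
                 null_max = max(null_counts),
                 n_perm = n_perm,
                 empirical_p = (1 + sum(null_counts >= observed)) /
                   (1 + n_perm)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Interval-overlap permutation test\n")
  cat(sprintf("  observed intersecting intervals: %d\n", x$observed_count))
  cat(sprintf("  null (%d permutations): mean %.1f, range %d-%d\n",
              x$n_perm, x$null_mean, x$null_min, x$null_max))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}
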