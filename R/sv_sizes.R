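#' Filter an indel/SV call set
#'
#' Applies the standard exclusion cascade: keep calls on allowed
#' chromosomes, longer than `min_size` bp (strict: size `min_size + 1`
#' survives, matching a "longer than" rule), not overlapping (>= 1 bp) any
#' exclude interval — assembly gaps, self-alignment segmental duplications,
#' read-depth segmental duplications — and, optionally, flagged as precise.
#'
#' @param calls Call data.frame (`chrom`, `start`, `end`, `type`, `size`,
#'   optional `precise`); see [read_indel_calls()].
#' @param gaps,sd_self,sd_depth Optional exclude interval sets.
#' @param layout Optional genome layout restricting the allowed chromosomes.
#' @param min_size Minimum size in bp, exclusive (default 10).
#' @param require_precise Drop calls with `precise == FALSE` (default FALSE).
#' @return The surviving subset of `calls` (row order preserved).
#' @export
filter_calls <- function(calls, gaps = NULL, sd_self = NULL, sd_depth = NULL,
                         layout = NULL, min_size = 10,
                         require_precise = FALSE) {
  validate_intervals(calls, "calls")
  keep <- calls$size > min_size
  if (!is.null(layout)) keep <- keep & calls$chrom %in% layout$chrom
  if (require_precise && !is.null(calls$precise))
    keep <- keep & calls$precise
  iv <- calls[, c("chrom", "start", "end")]
  for (excl in list(gaps, sd_self, sd_depth))
    if (!is.null(excl) && nrow(excl)) keep <- keep & !overlaps_any(iv, excl)
  calls[keep, , drop = FALSE]
}

#' Log-binned size histogram of indel calls
#'
#' Bins call sizes into bins of equal width on a logarithmic scale: bin k
#' spans `[min_size * 10^(k/bpd), min_size * 10^((k+1)/bpd))` with
#' `bpd = bins_per_decade`. Counts are reported separately per call type;
#' sizes outside `[min_size, max_size)` are excluded (and reported).
#'
#' @param calls Call data.frame with `type` and `size`.
#' @param bins_per_decade Number of bins per factor of 10 (default 10).
#' @param min_size Left edge of the first bin (default 10).
#' @param max_size Upper size limit (default 1e5).
#' @return Object of class `size_histogram`: data.frame `bin`, `lower`,
#'   `upper`, `insertion`, `deletion`, plus attributes.
#' @export
size_histogram <- function(calls, bins_per_decade = 10, min_size = 10,
                           max_size = 1e5) {
  stopifnot(bins_per_decade >= 1, min_size > 0, max_size > min_size)
  k_max <- ceiling(bins_per_decade * log10(max_size / min_size))
  edges <- min_size * 10^((0:k_max) / bins_per_decade)
  in_range <- calls$size >= min_size & calls$size < max_size
  tab <- data.frame(bin = seq_len(k_max) - 1L,
                    lower = edges[-length(edges)], upper = edges[-1L])
  for (ty in c("insertion", "deletion")) {
    s <- calls$size[in_range & calls$type == ty]
    # half-open bins [lower, upper)
    idx <- findInterval(s, edges, rightmost.closed = FALSE)
    tab[[ty]] <- tabulate(idx, nbins = k_max)
  }
  structure(tab, class = c("size_histogram", "data.frame"),
            bins_per_decade = bins_per_decade, min_size = min_size,
            max_size = max_size, n_out_of_range = sum(!in_range))
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf(
    "Log-binned size histogram: %d bins (%g/decade), sizes [%g, %g)\n",
    nrow(x), attr(x, "bins_per_decade"), attr(x, "min_size"),
    attr(x, "max_size")))
  cat(sprintf("  insertions: %d, deletions: %d, out of range: %d\n",
              sum(x$insertion), sum(x$deletion), attr(x, "n_out_of_range")))
  nz <- x[x$insertion + x$deletion > 0, , drop = FALSE]
  if (nrow(nz)) print.data.frame(utils::head(nz, 12), row.names = FALSE)
  invisible(x)
}

#' Plot a size histogram
#'
#' Log-x barplot of insertion and deletion size spectra; SINE-length
#' (~200 bp) and LINE-length (~6 kb) peaks show up as paired modes.
#'
#' @param x A [size_histogram()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.size_histogram <- function(x, ...) {
  mids <- sqrt(x$lower * x$upper)
  ylim <- c(0, max(x$insertion, x$deletion, 1))
  graphics::plot(mids, x$deletion, type = "h", log = "x", col = "firebrick",
                 lwd = 3, xlab = "size (bp)", ylab = "calls", ylim = ylim,
                 ...)
  graphics::points(mids * 1.12, x$insertion, type = "h", col = "steelblue",
                   lwd = 3)
  graphics::legend("topright", legend = c("deletion", "insertion"),
                   col = c("firebrick", "steelblue"), lwd = 3, bty = "n")
  invisible(x)
}

#' Count calls at dimorphic mobile-element sizes
#'
#' Counts calls whose size falls in the SINE-length and LINE-length windows
#' (defaults 150–250 bp and 5–7 kb, around the characteristic ~200 bp and
#' ~6 kb peaks of dimorphic carnivore SINEs and LINEs), per call type, with
#' the fraction of all calls each count represents.
#'
#' @param calls Call data.frame with `type` and `size`.
#' @param sine_range,line_range Inclusive size windows in bp; must not
#'   overlap.
#' @return List with per-type counts for each range and `fraction` of total
#'   calls.
#' @export
dimorphic_peak_counts <- function(calls, sine_range = c(150, 250),
                                  line_range = c(5000, 7000)) {
  stopifnot(length(sine_range) == 2L, length(line_range) == 2L)
  if (max(min(sine_range), min(line_range)) <=
      min(max(sine_range), max(line_range)) &&
      !(sine_range[2] < line_range[1] || line_range[2] < sine_range[1]))
    stop("sine_range and line_range must not overlap")
  count_in <- function(rng, ty)
    sum(calls$type == ty & calls$size >= rng[1] & calls$size <= rng[2])
  n <- nrow(calls)
  res <- list(
    sine = list(insertion = count_in(sine_range, "insertion"),
                deletion = count_in(sine_range, "deletion")),
    line = list(insertion = count_in(line_range, "insertion"),
                deletion = count_in(line_range, "deletion")))
  res$fraction <- list(
    sine = (res$sine$insertion + res$sine$deletion) / max(n, 1L),
    line = (res$line$insertion + res$line$deletion) / max(n, 1L))
  res
}
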