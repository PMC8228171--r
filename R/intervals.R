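#' Genomic intervals
#'
#' Construct and validate a set of genomic intervals. Coordinates follow the
#' BED convention throughout the package: 0-based, half-open `[start, end)`.
#' Human-readable reports render 1-based inclusive spans, but every function
#' in this package consumes and produces 0-based half-open coordinates.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start,end Integer-valued vectors with `0 <= start < end`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the interval invariants (`0 <= start < end`, non-empty `chrom`,
#' integer-valued coordinates) and stops with an informative error on the
#' first violation.
#'
#' @param x A data.frame with columns `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval set") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " must be a data.frame with columns chrom, start, end")
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!nzchar(x$chrom) | is.na(x$chrom)))
    stop(what, ": empty or missing chromosome name")
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end |
                 x$start != floor(x$start) | x$end != floor(x$end))
  if (length(bad))
    stop(what, ": invalid coordinates (need 0 <= start < end, integers) at row ",
         bad[1L])
  invisible(x)
}

#' Genome layout
#'
#' An ordered table of chromosome names and lengths; the coordinate system
#' every other stage works against.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Positive integer-valued lengths in bp.
#' @return A `data.frame` with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_layout <- function(chrom, length) {
  x <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$chrom)) stop("duplicate chromosome names in layout")
  if (any(!nzchar(x$chrom))) stop("empty chromosome name in layout")
  if (any(is.na(x$length) | x$length <= 0 | x$length != floor(x$length)))
    stop("chromosome lengths must be positive integers")
  x
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("chromosome not in layout: ", chrom[which(is.na(i))[1L]])
  layout$length[i]
}

#' Merge overlapping or adjacent intervals
#'
#' Collapses a set of intervals into its union: a sorted set of disjoint
#' intervals. Book-ended intervals (`end == next start`) are merged.
#'
#' @param x Interval data.frame.
#' @return Merged, sorted interval data.frame.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) return(x[, c("chrom", "start", "end")])
  x <- x[interval_order(x$chrom, x$start, x$end), , drop = FALSE]
  out_chrom <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  cur_chrom <- x$chrom[1L]; cur_start <- x$start[1L]; cur_end <- x$end[1L]
  for (i in seq_len(nrow(x))[-1L]) {
    if (x$chrom[i] == cur_chrom && x$start[i] <= cur_end) {
      cur_end <- max(cur_end, x$end[i])
    } else {
      out_chrom <- c(out_chrom, cur_chrom)
      out_start <- c(out_start, cur_start)
      out_end <- c(out_end, cur_end)
      cur_chrom <- x$chrom[i]; cur_start <- x$start[i]; cur_end <- x$end[i]
    }
  }
  data.frame(chrom = c(out_chrom, cur_chrom),
             start = c(out_start, cur_start),
             end = c(out_end, cur_end), stringsAsFactors = FALSE)
}

#' Which intervals of A overlap B?
#'
#' Overlap means >= 1 bp shared on the same chromosome (half-open semantics).
#'
#' @param a,b Interval data.frames.
#' @return Logical vector along the rows of `a`.
#' @export
overlaps_any <- function(a, b) {
  validate_intervals(a, "A"); validate_intervals(b, "B")
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  bm <- merge_intervals(b)
  hit <- rep(FALSE, nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- bm[bm$chrom == ch, , drop = FALSE]
    if (nrow(bi) == 0L) next
    # merged intervals are disjoint and sorted: starts and ends both increase
    idx <- findInterval(a$end[ai] - 1, bi$start)   # last b with start < a.end
    ok <- idx >= 1L
    ok[ok] <- bi$end[idx[ok]] > a$start[ai][ok]
    hit[ai] <- ok
  }
  hit
}

#' Count intervals of A that intersect B
#'
#' The enrichment statistic: the number of intervals in `a` that overlap
#' (>= 1 bp, same chromosome) at least one interval of `b`. Each interval of
#' `a` is counted at most once however many `b` intervals it touches.
#'
#' @param a,b Interval data.frames.
#' @return A single integer count.
#' @examples
#' a <- genomic_intervals("chr1", c(0, 100), c(50, 200))
#' b <- genomic_intervals("chr1", 40, 60)
#' count_intersecting(a, b)  # 1
#' @export
count_intersecting <- function(a, b) {
  sum(overlaps_any(a, b))
}

#' Total bp covered by an interval set
#' @param x Interval data.frame.
#' @return Total bases covered by the union of `x`.
#' @export
interval_footprint_bp <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0L) return(0)
  sum(m$end - m$start)
}

# Complement of `x` within the layout: per chromosome, the uncovered gaps.
complement_intervals <- function(x, layout) {
  m <- merge_intervals(x)
  out <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]; L <- layout$length[i]
    mi <- m[m$chrom == ch, , drop = FALSE]
    starts <- c(0, mi$end); ends <- c(mi$start, L)
    keep <- starts < ends
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = starts[keep],
                                            end = ends[keep],
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
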