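#' Concordance bounds for clone insert sizes
#'
#' The expected insert-size range of the clone library: an inward pair whose
#' implied fragment size falls inside `[min_insert, max_insert]` (inclusive
#' on both ends) is concordant. Defaults are the fosmid library bounds
#' 35,328–43,453 bp.
#'
#' @param min_insert,max_insert Insert-size bounds in bp.
#' @return A list of class `concordance_bounds`.
#' @export
concordance_bounds <- function(min_insert = 35328, max_insert = 43453) {
  if (!(0 < min_insert && min_insert < max_insert))
    stop("need 0 < min_insert < max_insert")
  structure(list(min_insert = min_insert, max_insert = max_insert),
            class = "concordance_bounds")
}

#' Implied clone fragment of an end pair
#'
#' The reference interval spanned by a same-chromosome end pair: from the
#' leftmost end position to the rightmost end position plus the read length.
#' Interchromosomal pairs have no implied fragment (NA row).
#'
#' @param pairs End-pair data.frame (see [read_pair_table()]).
#' @return data.frame with `clone_id`, `chrom`, `start`, `end`, `size`; NA
#'   coordinates for interchromosomal pairs.
#' @examples
#' p <- data.frame(clone_id = "c1", chrom_a = "chr1", pos_a = 100000,
#'                 strand_a = "+", chrom_b = "chr1", pos_b = 139000,
#'                 strand_b = "-", read_len = 500)
#' implied_fragment(p)  # size 39,500
#' @export
implied_fragment <- function(pairs) {
  same <- pairs$chrom_a == pairs$chrom_b
  start <- ifelse(same, pmin(pairs$pos_a, pairs$pos_b), NA)
  end <- ifelse(same, pmax(pairs$pos_a, pairs$pos_b) + pairs$read_len, NA)
  data.frame(clone_id = pairs$clone_id,
             chrom = ifelse(same, pairs$chrom_a, NA),
             start = start, end = end, size = end - start,
             stringsAsFactors = FALSE)
}

PAIR_CLASSES <- c("concordant", "discordant_size_short", "discordant_size_long",
                  "everted", "same_strand", "interchromosomal")

#' Classify end pairs
#'
#' Assigns each end pair to exactly one of six mutually exclusive classes:
#' \describe{
#'   \item{interchromosomal}{ends on different chromosomes.}
#'   \item{same_strand}{both ends on the same strand.}
#'   \item{everted}{opposite strands but outward-pointing (the leftmost read
#'     on the minus strand) — the tandem-duplication signature. Orientation
#'     alone decides; the implied size is ignored.}
#'   \item{concordant}{inward with implied size inside the bounds
#'     (inclusive).}
#'   \item{discordant_size_short / discordant_size_long}{inward but with
#'     implied size below / above the bounds.}
#' }
#' Ends at equal positions with opposite strands are treated as inward.
#'
#' @param pairs End-pair data.frame.
#' @param bounds A [concordance_bounds()].
#' @return Factor of classes along the rows of `pairs`.
#' @export
classify_pairs <- function(pairs, bounds = concordance_bounds()) {
  stopifnot(inherits(bounds, "concordance_bounds"))
  frag <- implied_fragment(pairs)
  n <- nrow(pairs)
  cls <- character(n)
  inter <- pairs$chrom_a != pairs$chrom_b
  same <- !inter & pairs$strand_a == pairs$strand_b
  # strand of the leftmost read (ties -> the + read counts as leftmost)
  left_minus <- !inter & !same &
    ifelse(pairs$pos_a == pairs$pos_b, FALSE,
           ifelse(pairs$pos_a < pairs$pos_b,
                  pairs$strand_a == "-", pairs$strand_b == "-"))
  cls[inter] <- "interchromosomal"
  cls[same] <- "same_strand"
  cls[left_minus] <- "everted"
  inward <- !inter & !same & !left_minus
  cls[inward & frag$size < bounds$min_insert] <- "discordant_size_short"
  cls[inward & frag$size > bounds$max_insert] <- "discordant_size_long"
  cls[inward & frag$size >= bounds$min_insert &
        frag$size <= bounds$max_insert] <- "concordant"
  factor(cls, levels = PAIR_CLASSES)
}

#' Physical coverage of clone fragments in fixed windows
#'
#' Tiles each chromosome with non-overlapping windows of `window` bp from
#' position 0 (final partial window included) and counts, per window, the
#' number of fragments overlapping it by at least 1 bp. Each fragment is
#' counted once per window however large the overlap.
#'
#' @param fragments Interval data.frame of (typically concordant) clone
#'   fragments.
#' @param layout Genome layout; fragments on chromosomes absent from the
#'   layout raise an error.
#' @param window Window size in bp (default 5000).
#' @return Coverage track: data.frame `chrom`, `start`, `end`, `count`, with
#'   attribute `window`.
#' @export
physical_coverage <- function(fragments, layout, window = 5000) {
  validate_intervals(fragments, "fragments")
  stopifnot(window >= 1)
  if (nrow(fragments) && !all(fragments$chrom %in% layout$chrom))
    stop("fragment chromosome absent from layout: ",
         setdiff(fragments$chrom, layout$chrom)[1L])
  out <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]; L <- layout$length[i]
    nw <- ceiling(L / window)
    counts <- numeric(nw)
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(f)) {
      if (any(f$end > L)) stop("fragment beyond end of ", ch)
      first <- floor(f$start / window) + 1L        # 1-based window index
      last <- floor((f$end - 1) / window) + 1L
      delta <- numeric(nw + 1L)
      for (j in seq_len(nrow(f))) {
        delta[first[j]] <- delta[first[j]] + 1
        delta[last[j] + 1L] <- delta[last[j] + 1L] - 1
      }
      counts <- cumsum(delta[seq_len(nw)])
    }
    starts <- (seq_len(nw) - 1L) * window
    out[[i]] <- data.frame(chrom = ch, start = starts,
                           end = pmin(L, starts + window), count = counts,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "window") <- window
  res
}

#' Extract unsupported (zero-coverage) intervals
#'
#' Maximal runs of zero-count windows are merged into candidate-misassembly
#' intervals. Any run containing the first or last window of its chromosome
#' is discarded (chromosome ends are expected to lack spanning clones), so an
#' all-zero chromosome yields no output.
#'
#' @param track Coverage track from [physical_coverage()].
#' @param layout Genome layout the track was computed on.
#' @return Sorted interval data.frame of unsupported segments.
#' @export
unsupported_intervals <- function(track, layout) {
  out <- list()
  for (ch in layout$chrom) {
    t <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(t) == 0L) next
    t <- t[order(t$start), , drop = FALSE]
    r <- rle(t$count == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    zi <- which(r$values)
    for (k in zi) {
      if (starts[k] == 1L || ends[k] == nrow(t)) next  # touches chromosome end
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = t$start[starts[k]], end = t$end[ends[k]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[interval_order(res$chrom, res$start, res$end), , drop = FALSE]
}

#' End-to-end concordance screen
#'
#' Convenience wrapper: classify pairs, compute physical coverage of the
#' concordant fragments, and extract unsupported intervals.
#'
#' @param pairs End-pair data.frame.
#' @param layout Genome layout.
#' @param bounds A [concordance_bounds()].
#' @param window Coverage window (bp).
#' @return List with `classes` (factor), `coverage` (track), `unsupported`
#'   (intervals) and `summary` (class counts and median window coverage).
#' @export
concordance_screen <- function(pairs, layout, bounds = concordance_bounds(),
                               window = 5000) {
  cls <- classify_pairs(pairs, bounds)
  frag <- implied_fragment(pairs)
  conc <- frag[!is.na(frag$chrom) & cls == "concordant", , drop = FALSE]
  cov <- physical_coverage(conc[, c("chrom", "start", "end")], layout, window)
  uns <- unsupported_intervals(cov, layout)
  list(classes = cls, coverage = cov, unsupported = uns,
       summary = list(class_counts = as.list(table(cls)),
                      n_pairs = nrow(pairs),
                      median_coverage = stats::median(cov$count),
                      n_unsupported = nrow(uns),
                      unsupported_bp = interval_footprint_bp(uns)))
}
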