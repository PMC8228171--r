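#' Build copy-number windows with fixed unmasked content
#'
#' Tiles each chromosome left to right with non-overlapping windows, each
#' closing as soon as it has accumulated `unmasked_target` bp of unmasked
#' sequence; the genomic span therefore stretches over masked regions. The
#' terminal remainder window is emitted with its actual unmasked count.
#'
#' @param layout Genome layout.
#' @param mask Optional interval data.frame of masked (repeat) sequence.
#' @param unmasked_target Unmasked bp per window (default 3000).
#' @return data.frame `chrom`, `start`, `end`, `unmasked_bp`, with attribute
#'   `unmasked_target`.
#' @export
make_cn_windows <- function(layout, mask = NULL, unmasked_target = 3000) {
  stopifnot(unmasked_target >= 1)
  if (is.null(mask))
    mask <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  validate_intervals(mask, "mask")
  if (nrow(mask) && !all(mask$chrom %in% layout$chrom))
    stop("mask chromosome absent from layout")
  unmasked <- complement_intervals(mask, layout)
  out <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]; L <- layout$length[i]
    u <- unmasked[unmasked$chrom == ch, , drop = FALSE]
    u <- u[order(u$start), , drop = FALSE]
    win_start <- 0; acc <- 0
    starts <- numeric(0); ends <- numeric(0); um <- numeric(0)
    for (j in seq_len(nrow(u))) {
      s <- u$start[j]; e <- u$end[j]
      while (acc + (e - s) >= unmasked_target) {
        cut <- s + (unmasked_target - acc)   # bp position closing the window
        starts <- c(starts, win_start); ends <- c(ends, cut)
        um <- c(um, unmasked_target)
        win_start <- cut; s <- cut; acc <- 0
      }
      acc <- acc + (e - s)
    }
    if (win_start < L) {                     # terminal remainder window
      starts <- c(starts, win_start); ends <- c(ends, L); um <- c(um, acc)
    }
    if (length(starts))
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = starts,
                                            end = ends, unmasked_bp = um,
                                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               unmasked_bp = numeric(0))
  attr(res, "unmasked_target") <- unmasked_target
  res
}

#' Estimate diploid copy number per window
#'
#' The copy number of a window is twice its per-unmasked-bp depth divided by
#' the control per-unmasked-bp depth:
#' `CN(w) = 2 * rate(w) / rate(control)`, where the control statistic is the
#' mean per-window rate over all windows overlapping (>= 1 bp) a control
#' region. Control regions are assumed copy-number 2.
#'
#' @param depth Depth track (`chrom`, `start`, `end`, `unmasked_bp`,
#'   `depth`), typically from [simulate_depth()] or [read_depth_track()].
#' @param controls Interval data.frame of control (CN = 2) regions.
#' @param stat Control summary: `"mean"` (default) or `"median"` of the
#'   per-window rates.
#' @return The depth track with columns `cn` (estimated diploid copy number;
#'   NA where `unmasked_bp` is 0) and `control` (logical) appended; attribute
#'   `control_rate` records the normaliser.
#' @export
estimate_copy_number <- function(depth, controls, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  validate_intervals(depth, "depth track")
  rate <- ifelse(depth$unmasked_bp > 0, depth$depth / depth$unmasked_bp, NA)
  is_control <- overlaps_any(depth[, c("chrom", "start", "end")], controls)
  ctrl_rates <- rate[is_control & !is.na(rate)]
  if (!length(ctrl_rates) || all(ctrl_rates == 0))
    stop("control regions have no usable depth")
  control_rate <- if (stat == "mean") mean(ctrl_rates) else
    stats::median(ctrl_rates)
  depth$cn <- 2 * rate / control_rate
  depth$control <- is_control
  attr(depth, "control_rate") <- control_rate
  attr(depth, "unmasked_target") <- attr(depth, "unmasked_target") %||%
    max(depth$unmasked_bp)
  depth
}

#' Call segmental duplications from copy-number windows
#'
#' A duplication is a maximal run of at least `min_run` consecutive windows
#' (adjacent in the window list, same chromosome) with estimated copy number
#' at least `min_cn` (inclusive thresholds). A single sub-threshold window
#' breaks a run, and runs never bridge chromosomes. Windows with less than
#' `min_unmasked_frac` of the target unmasked content (short terminal
#' windows) are excluded and break runs.
#'
#' @param cn_windows Output of [estimate_copy_number()].
#' @param min_run Minimum run length in windows (default 4).
#' @param min_cn Copy-number threshold (default 2.5).
#' @param min_unmasked_frac Minimum unmasked fraction of the window target
#'   for a window to be eligible (default 0.5).
#' @return data.frame of calls: `chrom`, `start`, `end`, `n_windows`,
#'   `mean_cn`.
#' @export
call_duplications <- function(cn_windows, min_run = 4, min_cn = 2.5,
                              min_unmasked_frac = 0.5) {
  stopifnot(min_run >= 1)
  target <- attr(cn_windows, "unmasked_target") %||% max(cn_windows$unmasked_bp)
  out <- list()
  for (ch in unique(cn_windows$chrom)) {
    w <- cn_windows[cn_windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    ok <- !is.na(w$cn) & w$cn >= min_cn &
      w$unmasked_bp >= min_unmasked_frac * target
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      i0 <- starts[k]; i1 <- ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = w$start[i0], end = w$end[i1],
        n_windows = i1 - i0 + 1L, mean_cn = mean(w$cn[i0:i1]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      mean_cn = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[interval_order(res$chrom, res$start, res$end), , drop = FALSE]
}

#' Filter assembly self-alignment duplication records
#'
#' Retains self-alignment records with percent identity and alignment length
#' at or above the thresholds (both inclusive; defaults 90% and 1 kb), and
#' returns the merged genomic footprint of both intervals of every retained
#' record.
#'
#' @param records data.frame with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `identity` (percent, 0-100), `length` (bp).
#' @param min_identity Minimum percent identity (default 90).
#' @param min_len Minimum alignment length in bp (default 1000).
#' @return List with `retained` (filtered records) and `footprint` (merged
#'   interval data.frame).
#' @export
filter_self_alignment_dups <- function(records, min_identity = 90,
                                       min_len = 1000) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "identity", "length")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("self-alignment table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(records) && any(records$identity < 0 | records$identity > 100))
    stop("identity must lie in [0, 100]")
  keep <- records$identity >= min_identity & records$length >= min_len
  retained <- records[keep, , drop = FALSE]
  both <- rbind(
    data.frame(chrom = retained$chrom1, start = retained$start1,
               end = retained$end1, stringsAsFactors = FALSE),
    data.frame(chrom = retained$chrom2, start = retained$start2,
               end = retained$end2, stringsAsFactors = FALSE))
  list(retained = retained, footprint = merge_intervals(both))
}
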