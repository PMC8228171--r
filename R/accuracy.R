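#' Alignment scoring scheme
#'
#' Scores for the global aligner: DNA defaults of match 5, mismatch -4,
#' gap open 16, gap extend 4 (a gap of length L costs
#' `gap_open + gap_extend * L`). IUPAC ambiguity codes always score as
#' mismatches.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (<= 0 by convention).
#' @param gap_open,gap_extend Gap penalties, `gap_open >= gap_extend >= 0`.
#' @return List of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = 16,
                           gap_extend = 4) {
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Optimal global alignment of two DNA sequences
#'
#' Score-maximal global (end-to-end) alignment under affine gap penalties,
#' computed by dynamic programming with a deterministic traceback that
#' prefers the diagonal, then a gap in B, then a gap in A on score ties.
#' With `band > 0` the DP is restricted to diagonals within `band` of the
#' main diagonal, which is exact whenever the optimal path stays inside the
#' band — appropriate for near-identical sequences such as finished clones
#' against their assembly locus.
#'
#' @param a,b DNA sequences (character scalars or anything `as.character`
#'   renders as one, e.g. a `DNAString`). Must be non-empty.
#' @param scoring A [scoring_scheme()].
#' @param band Diagonal band half-width in bp; 0 (default) runs the full
#'   quadratic DP.
#' @return Object of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `score`, `scoring`.
#' @examples
#' aln <- global_align("ACGT", "AGGT")
#' aln$score  # 3 matches + 1 mismatch = 11
#' @export
global_align <- function(a, b, scoring = scoring_scheme(), band = 0) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) != 1L || length(b) != 1L || !nzchar(a) || !nzchar(b))
    stop("sequences must be single non-empty strings")
  res <- align_affine_cpp(a, b, as.integer(scoring$match),
                          as.integer(scoring$mismatch),
                          as.integer(scoring$gap_open),
                          as.integer(scoring$gap_extend), as.integer(band))
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, scoring = scoring),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  n <- nchar(x$aligned_a)
  cat("Global alignment,", n, "columns, score", x$score, "\n")
  show <- min(n, width)
  cat(" A: ", substr(x$aligned_a, 1, show), if (n > width) "...", "\n",
      " B: ", substr(x$aligned_b, 1, show), if (n > width) "...", "\n",
      sep = "")
  invisible(x)
}

#' Column-level alignment accounting
#'
#' Counts alignment columns by category: `aligned_nucleotides` (a base in
#' both rows), split into `matches` (identical A/C/G/T) and `mismatches`
#' (everything else, including ambiguity codes), plus gap columns per row
#' and `gap_openings` (maximal gap runs in either row).
#'
#' @param aln A [global_align()] result, or a list with `aligned_a` and
#'   `aligned_b`.
#' @return List of class `column_counts`.
#' @export
column_counts <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  ga <- ca == "-"; gb <- cb == "-"
  if (any(ga & gb)) stop("column with gaps in both rows")
  both <- !ga & !gb
  matches <- sum(both & ca == cb & ca %in% c("A", "C", "G", "T"))
  runs <- function(g) sum(rle(g)$values)
  structure(list(aligned_nucleotides = sum(both), matches = matches,
                 mismatches = sum(both) - matches,
                 gap_columns_a = sum(ga), gap_columns_b = sum(gb),
                 gap_openings = runs(ga) + runs(gb)),
            class = "column_counts")
}

#' Phred-scaled per-base quality from a mismatch count
#'
#' `Q = -10 * log10(mismatches / aligned)`, rounded half-up to the nearest
#' integer. When `mismatches` is 0 a continuity floor of 0.5 observed
#' mismatches is applied so the estimate stays finite.
#'
#' @param mismatches Number of mismatching aligned columns (>= 0).
#' @param aligned Number of aligned nucleotide columns (> 0).
#' @return Integer Phred quality.
#' @examples
#' phred_quality(14255, 26778153)  # 33
#' @export
phred_quality <- function(mismatches, aligned) {
  if (aligned <= 0) stop("aligned must be positive")
  if (mismatches < 0 || mismatches > aligned)
    stop("mismatches must lie in [0, aligned]")
  m <- if (mismatches == 0) 0.5 else mismatches
  as.integer(round_half_up(-10 * log10(m / aligned)))
}

#' Pool per-clone accuracy counts
#'
#' Field-wise sums of per-clone column counts, with the Phred quality of the
#' pooled mismatch rate.
#'
#' @param counts A list of [column_counts()] results (or a data.frame with
#'   the same columns, one clone per row).
#' @return List with `pooled` (class `column_counts`) and `q` (integer
#'   Phred quality).
#' @export
aggregate_clone_accuracy <- function(counts) {
  if (is.data.frame(counts)) counts <- split(counts, seq_len(nrow(counts)))
  if (!length(counts)) stop("need at least one clone")
  fields <- c("aligned_nucleotides", "matches", "mismatches",
              "gap_columns_a", "gap_columns_b", "gap_openings")
  pooled <- lapply(fields, function(f)
    sum(vapply(counts, function(x) as.numeric(x[[f]]), 0)))
  names(pooled) <- fields
  class(pooled) <- "column_counts"
  list(pooled = pooled,
       q = phred_quality(pooled$mismatches, pooled$aligned_nucleotides))
}

#' @export
print.column_counts <- function(x, ...) {
  cat(sprintf(
    "aligned %d (matches %d, mismatches %d); gaps A %d, B %d; openings %d\n",
    x$aligned_nucleotides, x$matches, x$mismatches, x$gap_columns_a,
    x$gap_columns_b, x$gap_openings))
  invisible(x)
}

#' Align finished clones to their assembly placements
#'
#' For each clone, extracts the assembly sequence of its placement interval,
#' computes the global alignment, and accumulates column counts; reports
#' per-clone counts and the pooled Phred quality.
#'
#' @param clones Named sequences ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param assembly Named assembly sequences.
#' @param placements data.frame `clone_id`, `chrom`, `start`, `end` (0-based
#'   half-open interval of the assembly each clone aligns to).
#' @param scoring A [scoring_scheme()].
#' @param band Aligner band half-width (bp); clones are near-identical to
#'   their locus, so a modest band (default 200) is exact in practice.
#' @return List with `per_clone` (data.frame), `pooled` (column counts) and
#'   `q` (pooled Phred quality).
#' @export
align_clones <- function(clones, assembly, placements,
                         scoring = scoring_scheme(), band = 200) {
  cl <- as.character(clones); asm <- as.character(assembly)
  if (!all(placements$clone_id %in% names(cl)))
    stop("placement for unknown clone")
  rows <- vector("list", nrow(placements))
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    target <- substr(asm[[p$chrom]], p$start + 1, p$end)
    cc <- column_counts(global_align(cl[[p$clone_id]], target,
                                     scoring = scoring, band = band))
    rows[[i]] <- data.frame(clone_id = p$clone_id,
                            aligned = cc$aligned_nucleotides,
                            matches = cc$matches, mismatches = cc$mismatches,
                            gap_columns_a = cc$gap_columns_a,
                            gap_columns_b = cc$gap_columns_b,
                            gap_openings = cc$gap_openings,
                            stringsAsFactors = FALSE)
  }
  per_clone <- do.call(rbind, rows)
  counts <- lapply(rows, function(r)
    list(aligned_nucleotides = r$aligned, matches = r$matches,
         mismatches = r$mismatches, gap_columns_a = r$gap_columns_a,
         gap_columns_b = r$gap_columns_b, gap_openings = r$gap_openings))
  agg <- aggregate_clone_accuracy(counts)
  list(per_clone = per_clone, pooled = agg$pooled, q = agg$q)
}
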