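#' Cluster everted end pairs
#'
#' Single-linkage clustering of everted pairs on each chromosome: two pairs
#' are linked when their implied fragments are within `max_gap` bp of each
#' other (overlapping fragments have gap 0). Clusters with fewer than
#' `min_support` members are discarded. The reported junction estimate is
#' the median midpoint between the two everted end positions of the member
#' pairs — for a tandem duplication this concentrates near the midpoint of
#' the duplication unit, since everted ends flank the unit boundaries.
#'
#' @param pairs End-pair data.frame.
#' @param classes Pair classes from [classify_pairs()] (recomputed with
#'   default bounds when NULL).
#' @param max_gap Maximum fragment gap linking two pairs (bp, default
#'   10000).
#' @param min_support Minimum member pairs per cluster (default 3).
#' @return data.frame of clusters: `chrom`, `start`, `end` (member span),
#'   `n_pairs`, `junction` (bp), `members` (comma-joined clone ids).
#' @export
cluster_everted_pairs <- function(pairs, classes = NULL, max_gap = 10000,
                                  min_support = 3) {
  if (is.null(classes)) classes <- classify_pairs(pairs)
  ev <- pairs[classes == "everted", , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_pairs = integer(0),
                      junction = numeric(0), members = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) return(empty)
  frag <- implied_fragment(ev)
  frag$mid <- (pmin(ev$pos_a, ev$pos_b) +
                 pmax(ev$pos_a, ev$pos_b) + ev$read_len) / 2
  out <- list()
  for (ch in unique(frag$chrom)) {
    f <- frag[frag$chrom == ch, , drop = FALSE]
    f <- f[order(f$start, f$end), , drop = FALSE]
    # single-linkage on a line: chain while the gap to the running maximum
    # end stays within max_gap
    grp <- integer(nrow(f)); g <- 1L; grp[1L] <- 1L
    max_end <- f$end[1L]
    for (i in seq_len(nrow(f))[-1L]) {
      if (f$start[i] > max_end + max_gap) g <- g + 1L
      grp[i] <- g
      max_end <- max(max_end, f$end[i])
    }
    for (k in seq_len(g)) {
      m <- f[grp == k, , drop = FALSE]
      if (nrow(m) < min_support) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(m$start), end = max(m$end),
        n_pairs = nrow(m), junction = stats::median(m$mid),
        members = paste(m$clone_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[interval_order(res$chrom, res$start, res$end), , drop = FALSE]
}

#' Infer a tandem-duplication unit from split reads
#'
#' Reads spanning the copy-to-copy junction of a tandem duplication align as
#' two reference segments: one ending at the unit end, one starting at the
#' unit start. The unit is estimated robustly as
#' `end = median(seg1_end)`, `start = median(seg2_start)`. Noiseless input
#' recovers the unit exactly.
#'
#' @param splits Split-alignment data.frame (`chrom`, `seg1_start`,
#'   `seg1_end`, `seg2_start`, `seg2_end`), all on one chromosome.
#' @param min_support Minimum number of split records (default 3).
#' @return data.frame with one row: `chrom`, `start`, `end`, `length`,
#'   `support`. Errors if support is insufficient or the medians are
#'   inconsistent (`start >= end`).
#' @examples
#' s <- simulate_split_reads("chr6", 49729008, 49743863, 10, seed = 1)
#' infer_unit_from_split_reads(s)  # length 14,855 bp
#' @export
infer_unit_from_split_reads <- function(splits, min_support = 3) {
  if (nrow(splits) < min_support)
    stop("need at least ", min_support, " split records, got ", nrow(splits))
  if (length(unique(splits$chrom)) != 1L)
    stop("split records must be on a single chromosome")
  unit_end <- stats::median(splits$seg1_end)
  unit_start <- stats::median(splits$seg2_start)
  if (unit_start >= unit_end)
    stop("inconsistent split records: inferred start >= end")
  data.frame(chrom = splits$chrom[1L], start = unit_start, end = unit_end,
             length = unit_end - unit_start, support = nrow(splits),
             stringsAsFactors = FALSE)
}

#' Decompose an array copy number into structural alleles
#'
#' Enumerates every unordered assignment of a total diploid copy number to
#' `n_alleles` structural alleles, each carrying at least one copy, subject
#' to fixed-count constraints (a multiset of copy counts that must appear
#' among the alleles — e.g. one allele known to carry a single copy).
#'
#' @param total_cn Total diploid copy number (>= `n_alleles`).
#' @param n_alleles Number of structural alleles.
#' @param constraints Numeric vector of required per-allele copy counts
#'   (each matched to a distinct allele), or NULL.
#' @return Object of class `allele_decomposition`: `total_cn`, `n_alleles`,
#'   `constraints`, and `tuples` — a list of nondecreasing integer vectors,
#'   empty (with a diagnostic attribute) when the constraints are
#'   infeasible.
#' @examples
#' decompose_alleles(12, 3, constraints = 1)  # 5 feasible decompositions
#' @export
decompose_alleles <- function(total_cn, n_alleles, constraints = NULL) {
  stopifnot(total_cn >= 1, n_alleles >= 1)
  if (total_cn < n_alleles)
    stop("total_cn must be at least n_alleles (every allele carries >= 1)")
  parts <- partitions_fixed_length(total_cn, n_alleles)
  if (!is.null(constraints)) {
    constraints <- as.integer(constraints)
    if (length(constraints) > n_alleles)
      stop("more constraints than alleles")
    keep <- vapply(parts, function(p) {
      for (cst in constraints) {
        i <- match(cst, p)
        if (is.na(i)) return(FALSE)
        p <- p[-i]
      }
      TRUE
    }, TRUE)
    parts <- parts[keep]
  }
  structure(list(total_cn = total_cn, n_alleles = n_alleles,
                 constraints = constraints, tuples = parts),
            class = "allele_decomposition")
}

# All nondecreasing tuples of `k` positive integers summing to `n`
# (partitions of n into exactly k parts).
partitions_fixed_length <- function(n, k, min_part = 1) {
  if (k == 1L) {
    if (n >= min_part) return(list(n)) else return(list())
  }
  out <- list()
  if (min_part > n %/% k) return(out)
  for (first in min_part:(n %/% k)) {
    for (rest in partitions_fixed_length(n - first, k - 1L, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

#' @export
print.allele_decomposition <- function(x, ...) {
  cat(sprintf("Copy number %d over %d structural allele(s)", x$total_cn,
              x$n_alleles))
  if (length(x$constraints))
    cat(" with fixed count(s):", paste(x$constraints, collapse = ", "))
  cat("\n")
  if (!length(x$tuples)) {
    cat("  no feasible decomposition (constraints infeasible)\n")
  } else {
    cat(sprintf("  %d feasible decomposition(s):\n", length(x$tuples)))
    for (p in x$tuples) cat("   ", paste(p, collapse = " + "), "\n")
  }
  invisible(x)
}
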