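# Independent brute-force oracles. Deliberately naive: each recomputes its
# quantity by direct enumeration, sharing no code path with the package
# implementation it checks.

rand_intervals <- function(n, layout, max_len = 1000) {
  ch <- sample(layout$chrom, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  maxs <- layout$length[match(ch, layout$chrom)] - len
  ch <- ch[maxs >= 0]; len <- len[maxs >= 0]; maxs <- maxs[maxs >= 0]
  start <- floor(runif(length(ch), 0, maxs + 1))
  data.frame(chrom = ch, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# per-window fragment count by looping every window x fragment pair
oracle_coverage <- function(fragments, layout, window) {
  out <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]; L <- layout$length[i]
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(L, starts + window)
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    counts <- vapply(seq_along(starts), function(k)
      sum(f$start < ends[k] & f$end > starts[k]), 0L)
    out[[i]] <- data.frame(chrom = ch, start = starts, end = ends,
                           count = counts, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# zero runs minus end-touching runs, by direct scan
oracle_unsupported <- function(track, layout) {
  res <- list()
  for (ch in layout$chrom) {
    t <- track[track$chrom == ch, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    z <- t$count == 0
    i <- 1L
    while (i <= length(z)) {
      if (z[i]) {
        j <- i
        while (j < length(z) && z[j + 1L]) j <- j + 1L
        if (i > 1L && j < length(z))
          res[[length(res) + 1L]] <- data.frame(
            chrom = ch, start = t$start[i], end = t$end[j],
            stringsAsFactors = FALSE)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

# quadratic all-pairs overlap count
oracle_count_intersecting <- function(a, b) {
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          a$end[i] > b$start[j]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# run scanner for duplication calling
oracle_dup_calls <- function(cn_windows, min_run, min_cn, eligible) {
  res <- list()
  for (ch in unique(cn_windows$chrom)) {
    w <- cn_windows[cn_windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    ok <- eligible(w) & !is.na(w$cn) & w$cn >= min_cn
    i <- 1L
    while (i <= nrow(w)) {
      if (ok[i]) {
        j <- i
        while (j < nrow(w) && ok[j + 1L]) j <- j + 1L
        if (j - i + 1L >= min_run)
          res[[length(res) + 1L]] <- data.frame(
            chrom = ch, start = w$start[i], end = w$end[j],
            stringsAsFactors = FALSE)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

# union-find single-linkage of intervals linked when gap <= max_gap
oracle_single_linkage <- function(iv, max_gap) {
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || iv$chrom[i] != iv$chrom[j]) next
    gap <- max(iv$start[i], iv$start[j]) - min(iv$end[i], iv$end[j])
    if (gap <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Biostrings global alignment score (independent aligner)
oracle_align_score <- function(a, b, sc = scoring_scheme()) {
  iup <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K", "V", "H",
           "D", "B", "N")
  mat <- matrix(as.integer(sc$mismatch), 15, 15, dimnames = list(iup, iup))
  diag(mat)[1:4] <- as.integer(sc$match)
  as.integer(Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = sc$gap_open,
    gapExtension = sc$gap_extend)))
}

# direct per-size recount into explicit log bins
oracle_histogram <- function(sizes, bins_per_decade, min_size, max_size) {
  k_max <- ceiling(bins_per_decade * log10(max_size / min_size))
  counts <- integer(k_max)
  for (s in sizes) {
    if (s < min_size || s >= max_size) next
    for (k in seq_len(k_max)) {
      lo <- min_size * 10^((k - 1) / bins_per_decade)
      hi <- min_size * 10^(k / bins_per_decade)
      if (s >= lo && s < hi) { counts[k] <- counts[k] + 1L; break }
    }
  }
  counts
}

# character-wise substitution count between equal-length strings
oracle_string_diff <- function(x, y) {
  cx <- strsplit(x, "", fixed = TRUE)[[1L]]
  cy <- strsplit(y, "", fixed = TRUE)[[1L]]
  stopifnot(length(cx) == length(cy))
  sum(cx != cy)
}
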