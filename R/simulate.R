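#' Truth set for simulations
#'
#' Bundles the engineered events and rates that the simulators realise and
#' that recovery tests check against. Events are expressed in assembly
#' (reference) coordinates.
#'
#' Tandem duplications carry a copy count per haplotype (`copies_hap1`,
#' `copies_hap2`, both >= 1; 1 means no duplication on that haplotype), so a
#' heterozygous duplication is `(2, 1)` (diploid copy number 3 over the unit)
#' and a 12-copy diploid array is e.g. `(6, 6)`.
#'
#' Misassemblies describe errors of the assembly relative to the sample and
#' are applied to both haplotypes:
#' \describe{
#'   \item{inversion}{the assembly shows `[start, end)` reverse-complemented
#'     relative to the sample.}
#'   \item{insertion}{the assembly contains spurious sequence over
#'     `[start, end)` that is absent from the sample; no sample fragment can
#'     map inside it.}
#'   \item{deletion}{the assembly is missing sample sequence; the sample
#'     carries a novel insertion of length `end - start` at assembly
#'     position `start`.}
#' }
#'
#' @param duplications data.frame with columns `chrom`, `start`, `end`,
#'   `copies_hap1`, `copies_hap2`, or NULL.
#' @param misassemblies data.frame with columns `chrom`, `start`, `end`,
#'   `kind` (one of inversion/insertion/deletion), or NULL.
#' @param sub_rate,indel_rate Finished-clone per-bp error rates in `[0, 1)`.
#' @param mean_depth Baseline diploid depth (per unmasked bp) for depth
#'   simulation.
#' @return An object of class `truth_set`.
#' @export
truth_set <- function(duplications = NULL, misassemblies = NULL,
                      sub_rate = 0, indel_rate = 0, mean_depth = 30) {
  if (is.null(duplications))
    duplications <- data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0), copies_hap1 = numeric(0),
                               copies_hap2 = numeric(0))
  if (is.null(misassemblies))
    misassemblies <- data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), kind = character(0))
  validate_intervals(duplications, "duplications")
  validate_intervals(misassemblies, "misassemblies")
  if (nrow(duplications) &&
      any(duplications$copies_hap1 < 1 | duplications$copies_hap2 < 1))
    stop("duplication copy counts must be >= 1")
  if (nrow(misassemblies) &&
      !all(misassemblies$kind %in% c("inversion", "insertion", "deletion")))
    stop("misassembly kind must be inversion, insertion or deletion")
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("error rates must lie in [0, 1)")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  structure(list(duplications = duplications, misassemblies = misassemblies,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 mean_depth = mean_depth),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Truth set:", nrow(x$duplications), "duplication(s),",
      nrow(x$misassemblies), "misassembly(ies);",
      "sub_rate =", x$sub_rate, "indel_rate =", x$indel_rate,
      "mean_depth =", x$mean_depth, "\n")
  invisible(x)
}

# Events of a truth set restricted to one chromosome, sorted, with overlap
# and bounds checks against the layout.
chrom_events <- function(truth, layout, ch) {
  L <- chrom_length(layout, ch)
  d <- truth$duplications[truth$duplications$chrom == ch, , drop = FALSE]
  m <- truth$misassemblies[truth$misassemblies$chrom == ch, , drop = FALSE]
  ev <- rbind(
    if (nrow(d)) data.frame(start = d$start, end = d$end, kind = "dup",
                            copies_hap1 = d$copies_hap1,
                            copies_hap2 = d$copies_hap2),
    if (nrow(m)) data.frame(start = m$start, end = m$end, kind = m$kind,
                            copies_hap1 = 1, copies_hap2 = 1))
  if (is.null(ev) || nrow(ev) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      kind = character(0), copies_hap1 = numeric(0),
                      copies_hap2 = numeric(0)))
  if (any(ev$end > L)) stop("event beyond chromosome end on ", ch)
  ev <- ev[order(ev$start), , drop = FALSE]
  if (nrow(ev) > 1L && any(ev$start[-1L] < ev$end[-nrow(ev)]))
    stop("overlapping events on ", ch, " are not representable")
  ev
}

# Sample-haplotype segment table for one chromosome: each row is a
# contiguous sample segment mapping to reference [ref_start, ref_end) on
# `strand` (+/-), or to novel sequence (ref_start = NA, length novel_len).
# samp_start/samp_end give the segment's cumulative sample coordinates.
# `junction` marks segments whose sample start is a tandem-duplication
# copy-to-copy junction.
haplotype_segments <- function(truth, layout, ch, hap) {
  L <- chrom_length(layout, ch)
  ev <- chrom_events(truth, layout, ch)
  segs <- list()
  add <- function(rs, re, strand, novel = 0, junction = FALSE)
    segs[[length(segs) + 1L]] <<- data.frame(
      ref_start = rs, ref_end = re, strand = strand, novel_len = novel,
      junction = junction)
  pos <- 0
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; e <- ev$end[i]
    if (s > pos) add(pos, s, "+")
    k <- ev$kind[i]
    if (k == "dup") {
      copies <- if (hap == 1L) ev$copies_hap1[i] else ev$copies_hap2[i]
      for (cp in seq_len(copies)) add(s, e, "+", junction = cp > 1L)
    } else if (k == "inversion") {
      add(s, e, "-")
    } else if (k == "insertion") {
      # spurious assembly sequence: sample skips it
    } else if (k == "deletion") {
      add(NA, NA, "+", novel = e - s)
      add(s, e, "+")
    }
    pos <- e
  }
  if (pos < L) add(pos, L, "+")
  segs <- do.call(rbind, segs)
  len <- ifelse(is.na(segs$ref_start), segs$novel_len,
                segs$ref_end - segs$ref_start)
  segs$samp_start <- cumsum(c(0, len[-length(len)]))
  segs$samp_end <- segs$samp_start + len
  segs
}

# Map a read occupying sample interval [p, p + r) with sample-space strand
# `strand` back to reference space. Returns list(pos, strand) of the leftmost
# reference coordinate, or NULL if the read is unmappable (novel sequence or
# straddling a segment boundary, where a real aligner would split or drop).
map_read <- function(segs, p, r, strand) {
  i <- findInterval(p, segs$samp_start)
  if (i < 1L || p + r > segs$samp_end[i]) return(NULL)
  if (is.na(segs$ref_start[i])) return(NULL)
  q <- p - segs$samp_start[i]
  if (segs$strand[i] == "+") {
    list(pos = segs$ref_start[i] + q, strand = strand)
  } else {
    seg_len <- segs$ref_end[i] - segs$ref_start[i]
    list(pos = segs$ref_start[i] + seg_len - q - r,
         strand = if (strand == "+") "-" else "+")
  }
}

#' Simulate a random genome
#'
#' Generates i.i.d. uniform A/C/G/T sequence for each chromosome of the
#' layout. Used as the neutral background for all downstream simulators.
#'
#' @param layout Genome layout (see [genome_layout()]).
#' @param seed Integer seed; same seed, same genome.
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(layout, seed = NULL) {
  with_seed(seed, {
    seqs <- vapply(layout$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      "")
    Biostrings::DNAStringSet(stats::setNames(seqs, layout$chrom))
  })
}

#' Simulate clone end pairs
#'
#' Draws clone fragments on the sample haplotypes implied by the truth set
#' (two haplotypes mixed 50/50), with fragment lengths
#' Normal(`insert_mean`, `insert_sd`) truncated below at `2 * read_len`,
#' and maps both end reads back to reference (assembly) space through the
#' engineered events. Away from events pairs are inward and size-concordant;
#' a fragment spanning a tandem-duplication copy junction yields an everted
#' pair; fragments across misassembly breakpoints yield discordant or
#' unmappable ends. Pairs with an unmappable end are dropped from the pair
#' table (they are retained in the per-clone truth with `mapped = FALSE`).
#'
#' @param truth A [truth_set()].
#' @param layout Genome layout.
#' @param n_clones Number of fragments to draw.
#' @param insert_mean,insert_sd Fragment length distribution (bp).
#' @param read_len End-read length (bp).
#' @param seed Integer seed.
#' @return A list with `pairs` (the end-pair table, mappable pairs only) and
#'   `clones` (per-fragment truth: haplotype, sample coordinates, whether the
#'   fragment spans a duplication junction, whether both ends mapped).
#' @export
simulate_clone_pairs <- function(truth, layout, n_clones, insert_mean,
                                 insert_sd, read_len, seed = NULL) {
  stopifnot(n_clones > 0, insert_mean > 2 * read_len, insert_sd >= 0,
            read_len > 0)
  with_seed(seed, {
    # per (hap, chrom) segment tables and sample lengths
    segtabs <- list()
    for (hap in 1:2) for (ch in layout$chrom)
      segtabs[[paste(hap, ch)]] <- haplotype_segments(truth, layout, ch, hap)
    samp_len <- vapply(segtabs, function(s) max(s$samp_end), 0)

    hap <- sample(1:2, n_clones, replace = TRUE)
    ch <- character(n_clones)
    for (h in 1:2) {
      idx <- which(hap == h)
      if (!length(idx)) next
      w <- samp_len[paste(h, layout$chrom)]   # weight by sample-space length
      ch[idx] <- sample(layout$chrom, length(idx), replace = TRUE, prob = w)
    }
    key <- paste(hap, ch)
    flen <- pmax(2 * read_len,
                 round(stats::rnorm(n_clones, insert_mean, insert_sd)))
    rec <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      H <- samp_len[[key[i]]]
      fl <- min(flen[i], H)
      u <- floor(stats::runif(1, 0, H - fl + 1))
      segs <- segtabs[[key[i]]]
      a <- map_read(segs, u, read_len, "+")
      b <- map_read(segs, u + fl - read_len, read_len, "-")
      jx <- segs$samp_start[segs$junction]
      rec[[i]] <- list(
        ch = sub("^[12] ", "", key[i]), hap = as.integer(substr(key[i], 1, 1)),
        s = u, e = u + fl, mapped = !is.null(a) && !is.null(b),
        spans = any(jx > u & jx < u + fl),
        pa = if (is.null(a)) NA else a$pos,
        sa = if (is.null(a)) NA else a$strand,
        pb = if (is.null(b)) NA else b$pos,
        sb = if (is.null(b)) NA else b$strand)
    }
    clone_id <- sprintf("clone%06d", seq_len(n_clones))
    clones <- data.frame(
      clone_id = clone_id,
      hap = vapply(rec, `[[`, 0L, "hap"),
      chrom = vapply(rec, `[[`, "", "ch"),
      sample_start = vapply(rec, `[[`, 0, "s"),
      sample_end = vapply(rec, `[[`, 0, "e"),
      spans_dup_junction = vapply(rec, `[[`, TRUE, "spans"),
      mapped = vapply(rec, `[[`, TRUE, "mapped"),
      stringsAsFactors = FALSE)
    ok <- clones$mapped
    pairs <- data.frame(
      clone_id = clone_id[ok],
      chrom_a = clones$chrom[ok],
      pos_a = vapply(rec[ok], `[[`, 0, "pa"),
      strand_a = vapply(rec[ok], `[[`, "", "sa"),
      chrom_b = clones$chrom[ok],
      pos_b = vapply(rec[ok], `[[`, 0, "pb"),
      strand_b = vapply(rec[ok], `[[`, "", "sb"),
      read_len = read_len,
      stringsAsFactors = FALSE)
    list(pairs = pairs, clones = clones)
  })
}

#' Simulate a per-window depth track
#'
#' Window depth is drawn as Poisson with mean
#' `mean_diploid_depth * unmasked_bp * CN / 2`, where CN is the truth diploid
#' copy number averaged over the window: baseline 2, raised over tandem
#' duplications (`copies_hap1 + copies_hap2`), and 0 over spurious assembly
#' insertions (no sample DNA maps there). GC bias is deliberately not
#' modelled.
#'
#' @param truth A [truth_set()].
#' @param layout Genome layout.
#' @param windows Optional precomputed windows from [make_cn_windows()];
#'   built from `layout`/`mask`/`unmasked_target` when NULL.
#' @param mean_diploid_depth Expected depth per unmasked bp at CN 2.
#' @param mask Optional mask intervals.
#' @param unmasked_target Unmasked bp per window when building windows.
#' @param seed Integer seed.
#' @return A depth-track data.frame (`chrom`, `start`, `end`, `unmasked_bp`,
#'   `depth`).
#' @export
simulate_depth <- function(truth, layout, windows = NULL,
                           mean_diploid_depth = 30, mask = NULL,
                           unmasked_target = 3000, seed = NULL) {
  stopifnot(mean_diploid_depth > 0)
  if (is.null(windows))
    windows <- make_cn_windows(layout, mask = mask,
                               unmasked_target = unmasked_target)
  cn <- window_truth_cn(truth, windows)
  with_seed(seed, {
    lambda <- mean_diploid_depth * windows$unmasked_bp * cn / 2
    windows$depth <- stats::rpois(nrow(windows), lambda)
    windows[, c("chrom", "start", "end", "unmasked_bp", "depth")]
  })
}

# Truth diploid copy number averaged over each window's genomic span.
window_truth_cn <- function(truth, windows) {
  cn <- rep(2, nrow(windows))
  span <- windows$end - windows$start
  adjust <- function(iv, delta) {
    for (j in seq_len(nrow(iv))) {
      sel <- which(windows$chrom == iv$chrom[j] &
                     windows$start < iv$end[j] & windows$end > iv$start[j])
      if (!length(sel)) next
      ov <- pmin(windows$end[sel], iv$end[j]) -
        pmax(windows$start[sel], iv$start[j])
      cn[sel] <<- cn[sel] + delta[j] * ov / span[sel]
    }
  }
  d <- truth$duplications
  if (nrow(d)) adjust(d, d$copies_hap1 + d$copies_hap2 - 2)
  m <- truth$misassemblies[truth$misassemblies$kind == "insertion", ,
                           drop = FALSE]
  if (nrow(m)) adjust(m, rep(-2, nrow(m)))
  pmax(cn, 0)
}

#' Simulate finished clones with known errors
#'
#' Extracts random substrings of the assembly and injects substitutions
#' (per-bp Bernoulli(`sub_rate`), always to a different base) and 1-bp
#' indels (per-bp Bernoulli(`indel_rate`), insertion or deletion with equal
#' probability), recording the exact event counts per clone.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector).
#' @param n Number of clones.
#' @param clone_len Clone length in bp; must not exceed the shortest
#'   chromosome.
#' @param sub_rate,indel_rate Per-bp error rates.
#' @param seed Integer seed.
#' @return A list with `clones` (DNAStringSet) and `truth` (per-clone source
#'   placement plus `n_sub`, `n_ins`, `n_del`).
#' @export
simulate_finished_clones <- function(genome, n, clone_len, sub_rate = 0,
                                     indel_rate = 0, seed = NULL) {
  seqs <- as.character(genome)
  if (is.null(names(seqs))) stop("genome sequences must be named")
  if (clone_len > min(nchar(seqs)))
    stop("clone_len exceeds the shortest chromosome")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    w <- nchar(seqs) - clone_len + 1
    ch <- sample(names(seqs), n, replace = TRUE, prob = w)
    start <- floor(stats::runif(n, 0, w[ch]))
    out <- character(n); nsub <- nins <- ndel <- integer(n)
    for (i in seq_len(n)) {
      s <- substr(seqs[[ch[i]]], start[i] + 1, start[i] + clone_len)
      v <- strsplit(s, "", fixed = TRUE)[[1L]]
      sub_at <- which(stats::runif(clone_len) < sub_rate)
      for (p in sub_at) v[p] <- sample(setdiff(bases, v[p]), 1L)
      ind_at <- which(stats::runif(clone_len) < indel_rate)
      ins <- logical(length(ind_at))
      if (length(ind_at)) {
        ins <- stats::runif(length(ind_at)) < 0.5
        pieces <- v
        pieces[ind_at[!ins]] <- ""                       # deletions
        pieces[ind_at[ins]] <- paste0(sample(bases, sum(ins), replace = TRUE),
                                      v[ind_at[ins]])    # insert before base
        out[i] <- paste(pieces, collapse = "")
      } else out[i] <- paste(v, collapse = "")
      nsub[i] <- length(sub_at); nins[i] <- sum(ins); ndel[i] <- sum(!ins)
    }
    id <- sprintf("fclone%04d", seq_len(n))
    list(clones = Biostrings::DNAStringSet(stats::setNames(out, id)),
         truth = data.frame(clone_id = id, chrom = ch, start = start,
                            end = start + clone_len, n_sub = nsub,
                            n_ins = nins, n_del = ndel,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate split reads across a tandem-duplication junction
#'
#' Each simulated long read spans the copy-to-copy junction of a tandem
#' duplication with unit `[unit_start, unit_end)`, producing two
#' reference-space alignment segments: one ending at the unit end, one
#' starting at the unit start. Optional uniform jitter of up to `jitter` bp
#' is added independently to each breakpoint coordinate to emulate alignment
#' imprecision.
#'
#' @param chrom Chromosome name of the unit.
#' @param unit_start,unit_end Unit boundaries (0-based half-open).
#' @param n_reads Number of junction-spanning reads.
#' @param read_len Read length (bp).
#' @param jitter Maximum absolute breakpoint jitter (bp); 0 = noiseless.
#' @param seed Integer seed.
#' @return Split-alignment data.frame (`read_id`, `chrom`, `seg1_start`,
#'   `seg1_end`, `seg2_start`, `seg2_end`).
#' @export
simulate_split_reads <- function(chrom, unit_start, unit_end, n_reads,
                                 read_len = 10000, jitter = 0, seed = NULL) {
  stopifnot(unit_start < unit_end, n_reads >= 0, read_len >= 2, jitter >= 0)
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      seg1_start = numeric(0), seg1_end = numeric(0),
                      seg2_start = numeric(0), seg2_end = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_reads == 0L) return(empty)
  with_seed(seed, {
    d <- floor(stats::runif(n_reads, 1, read_len))  # bp of read before junction
    j1 <- if (jitter > 0) round(stats::runif(n_reads, -jitter, jitter)) else 0
    j2 <- if (jitter > 0) round(stats::runif(n_reads, -jitter, jitter)) else 0
    seg1_end <- unit_end + j1
    seg2_start <- unit_start + j2
    data.frame(read_id = sprintf("read%05d", seq_len(n_reads)),
               chrom = chrom,
               seg1_start = pmax(0, seg1_end - d),
               seg1_end = seg1_end,
               seg2_start = seg2_start,
               seg2_end = seg2_start + (read_len - d),
               stringsAsFactors = FALSE)
  })
}
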