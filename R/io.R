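#' Read a BED file
#'
#' Reads a 3+ column BED file into an interval table. `track`, `browser` and
#' `#` comment lines are skipped. Coordinates are kept verbatim (0-based,
#' half-open). Malformed lines raise an error naming the offending line
#' number.
#'
#' @param path Path to a BED file.
#' @return Interval data.frame (`chrom`, `start`, `end`); extra BED columns
#'   are returned as `name`, `score`, `strand` where present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track\\b|browser\\b|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0 | start >= end)
  if (length(bad))
    stop("BED line ", lineno[bad[1L]],
         ": malformed coordinates (need integers with 0 <= start < end)")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  extras <- c("name", "score", "strand")
  for (k in seq_along(extras)) {
    col <- k + 3L
    if (all(nf >= col)) out[[extras[k]]] <- vapply(fields, `[[`, "", col)
  }
  out
}

#' Write intervals as BED
#'
#' @param x Interval data.frame; a `name` column, if present, is written as
#'   BED column 4, and further recognised columns (`score`, `strand`) follow.
#' @param path Output path.
#' @param sort Sort by (chrom, start, end) before writing (lexicographic
#'   chromosome order, numeric start order). Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, sort = TRUE) {
  validate_intervals(x)
  if (sort && nrow(x))
    x <- x[interval_order(x$chrom, x$start, x$end), , drop = FALSE]
  cols <- c("chrom", "start", "end",
            intersect(c("name", "score", "strand"), names(x)))
  lines <- if (nrow(x) == 0L) character(0) else
    do.call(paste, c(lapply(cols, function(cn) format_plain(x[[cn]])),
                     sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# format numbers without scientific notation; pass characters through
format_plain <- function(v) {
  if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else
    as.character(v)
}

PAIR_COLS <- c("clone_id", "chrom_a", "pos_a", "strand_a",
               "chrom_b", "pos_b", "strand_b", "read_len")

#' Read a clone end-pair alignment table
#'
#' Tab-separated table with a header naming at least the columns
#' `clone_id, chrom_a, pos_a, strand_a, chrom_b, pos_b, strand_b, read_len`.
#' Positions are 0-based leftmost alignment coordinates of each end read;
#' strands are `+` or `-`.
#'
#' @param path Path to the TSV.
#' @return A data.frame with one row per end pair.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(PAIR_COLS, names(x))
  if (length(missing))
    stop("pair table is missing column(s): ", paste(missing, collapse = ", "))
  for (s in c("strand_a", "strand_b")) {
    bad <- which(!x[[s]] %in% c("+", "-"))
    if (length(bad))
      stop("pair table row ", bad[1L], ": unknown strand symbol '",
           x[[s]][bad[1L]], "' in ", s)
  }
  if (any(x$pos_a < 0 | x$pos_b < 0)) stop("pair table: negative position")
  x[, c(PAIR_COLS, setdiff(names(x), PAIR_COLS))]
}

#' Write a clone end-pair alignment table
#' @param pairs Pair data.frame (see [read_pair_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  missing <- setdiff(PAIR_COLS, names(pairs))
  if (length(missing))
    stop("pair table is missing column(s): ", paste(missing, collapse = ", "))
  write_tsv(pairs[, PAIR_COLS], path)
  invisible(path)
}

#' Read / write a genome layout table
#'
#' Two-column TSV (`chrom`, `length`) with header.
#' @param path File path.
#' @return [read_genome_layout()]: a layout data.frame.
#' @export
read_genome_layout <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(x)))
    stop("layout table needs columns chrom, length")
  genome_layout(x$chrom, x$length)
}

#' @rdname read_genome_layout
#' @param layout Layout data.frame.
#' @export
write_genome_layout <- function(layout, path) {
  write_tsv(layout[, c("chrom", "length")], path)
  invisible(path)
}

#' Read / write a per-window depth track
#'
#' TSV with header columns `chrom`, `start`, `end`, `unmasked_bp`, `depth`:
#' summed read depth over the unmasked positions of each window.
#' @param path File path.
#' @return [read_depth_track()]: a depth-track data.frame.
#' @export
read_depth_track <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "unmasked_bp", "depth")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("depth track is missing column(s): ", paste(missing, collapse = ", "))
  validate_intervals(x, "depth track")
  if (any(x$depth < 0)) stop("depth track: negative depth")
  if (any(x$unmasked_bp > x$end - x$start))
    stop("depth track: unmasked_bp exceeds window span")
  x
}

#' @rdname read_depth_track
#' @param track Depth-track data.frame.
#' @export
write_depth_track <- function(track, path) {
  write_tsv(track[, c("chrom", "start", "end", "unmasked_bp", "depth")], path)
  invisible(path)
}

#' Read an indel/SV call table
#'
#' Primary input is a TSV with header columns `chrom`, `start`, `end`,
#' `type` (`insertion`/`deletion`), `size` (bp) and optionally `precise`
#' (TRUE/FALSE). A path ending in `.vcf` is parsed instead as a minimal VCF
#' subset (CHROM, POS and the INFO keys SVTYPE, SVLEN; PRECISE/IMPRECISE
#' flags), via the vcfR package.
#'
#' @param path Path to the calls file.
#' @return Call data.frame with columns `chrom`, `start`, `end`, `type`,
#'   `size`, `precise`.
#' @export
read_indel_calls <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE))
    return(read_indel_vcf(path))
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "type", "size")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("call table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!x$type %in% c("insertion", "deletion"))
  if (length(bad))
    stop("call table row ", bad[1L], ": unknown type '", x$type[bad[1L]], "'")
  if (any(x$size <= 0)) stop("call table: sizes must be positive")
  if (is.null(x$precise)) x$precise <- TRUE
  x$precise <- as.logical(x$precise)
  validate_intervals(x, "call table")
  x
}

read_indel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package; supply a TSV instead")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])            # VCF is 1-based
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
  imprecise <- grepl("(^|;)IMPRECISE(;|$)", vcfR::getINFO(v))
  type <- ifelse(svtype == "INS", "insertion",
                 ifelse(svtype == "DEL", "deletion", NA_character_))
  keep <- !is.na(type) & !is.na(svlen)
  size <- abs(svlen[keep])
  start <- pos[keep] - 1
  end <- ifelse(type[keep] == "deletion", start + size, start + 1)
  data.frame(chrom = chrom[keep], start = start, end = end,
             type = type[keep], size = size, precise = !imprecise[keep],
             stringsAsFactors = FALSE)
}

# Deterministic TSV writer (fixed column order, no quoting, no row names).
write_tsv <- function(x, path) {
  for (cn in names(x)) x[[cn]] <- format_plain(x[[cn]])
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
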