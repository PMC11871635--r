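# Readers/writers for narrowPeak / BED peak calls and bedGraph signal.
#
# Files are 0-based half-open (BED convention); in memory everything is a
# GRanges (1-based closed), converted at this boundary and nowhere else.

split_fields <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  list(parts = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

field_col <- function(parts, i, default = NA_character_) {
  vapply(parts, function(p) if (length(p) >= i) p[[i]] else default,
         FUN.VALUE = character(1))
}

parse_coords <- function(parts, lineno) {
  start0 <- suppressWarnings(as.integer(field_col(parts, 2)))
  end0 <- suppressWarnings(as.integer(field_col(parts, 3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stop(sprintf("line %d: non-integer coordinates", lineno[bad[1]]),
         call. = FALSE)
  }
  bad <- which(start0 < 0 | end0 <= start0)
  if (length(bad)) {
    stop(sprintf("line %d: invalid interval (need 0 <= start < end)",
                 lineno[bad[1]]), call. = FALSE)
  }
  list(start0 = start0, end0 = end0)
}

sorted_granges <- function(gr) {
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Read peak calls from a narrowPeak or BED file
#'
#' Accepts MACS2 narrowPeak (BED6+4) as well as plain BED3-BED6. Missing
#' optional columns get defaults: name `"."`, score 0, strand `"*"`,
#' signalValue 0, pValue/qValue/peak -1.
#'
#' @param path Path to a tab-separated narrowPeak/BED file.
#' @return A [GenomicRanges::GRanges] with metadata columns `name`, `score`,
#'   `signalValue`, `pValue`, `qValue`, `peak`.
#' @export
read_narrowpeak <- function(path) {
  f <- split_fields(path)
  if (!length(f$parts)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = character(0), score = numeric(0), signalValue = numeric(0),
      pValue = numeric(0), qValue = numeric(0), peak = integer(0))
    return(gr)
  }
  nf <- lengths(f$parts)
  if (any(nf < 3)) {
    stop(sprintf("line %d: expected at least 3 tab-separated fields",
                 f$lineno[which(nf < 3)[1]]), call. = FALSE)
  }
  co <- parse_coords(f$parts, f$lineno)
  chrom <- field_col(f$parts, 1)
  name <- field_col(f$parts, 4); name[is.na(name)] <- "."
  score <- suppressWarnings(as.numeric(field_col(f$parts, 5)))
  score[is.na(score)] <- 0
  strand <- field_col(f$parts, 6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  sv <- suppressWarnings(as.numeric(field_col(f$parts, 7)))
  sv[is.na(sv)] <- 0
  bad <- which(sv < 0)
  if (length(bad)) {
    stop(sprintf("line %d: negative signalValue", f$lineno[bad[1]]),
         call. = FALSE)
  }
  pv <- suppressWarnings(as.numeric(field_col(f$parts, 8))); pv[is.na(pv)] <- -1
  qv <- suppressWarnings(as.numeric(field_col(f$parts, 9))); qv[is.na(qv)] <- -1
  pk <- suppressWarnings(as.integer(field_col(f$parts, 10))); pk[is.na(pk)] <- -1L
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = co$start0 + 1L, end = co$end0),
    strand = strand,
    name = name, score = score, signalValue = sv,
    pValue = pv, qValue = qv, peak = pk)
  sorted_granges(gr)
}

#' Write peaks as a 10-column narrowPeak file
#'
#' The canonical formatting (4 decimals for signalValue/pValue/qValue) is
#' byte-stable under a read/write round trip.
#'
#' @param peaks A `GRanges` as produced by [read_narrowpeak()].
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  strand_chr <- as.character(GenomicRanges::strand(peaks))
  strand_chr[strand_chr == "*"] <- "."
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
    as.character(GenomicRanges::seqnames(peaks)),
    GenomicRanges::start(peaks) - 1L,
    GenomicRanges::end(peaks),
    mc$name %||% rep(".", length(peaks)),
    as.integer(round(mc$score %||% rep(0, length(peaks)))),
    strand_chr,
    fmt_num(mc$signalValue %||% rep(0, length(peaks))),
    fmt_num(mc$pValue %||% rep(-1, length(peaks))),
    fmt_num(mc$qValue %||% rep(-1, length(peaks))),
    as.integer(mc$peak %||% rep(-1L, length(peaks))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4-column bedGraph signal track
#'
#' Steps are sorted per chromosome on load. Overlapping steps are rejected
#' (the dialect is ambiguous: some emitters mean "sum", some "override") and
#' so are negative values.
#'
#' @param path Path to a bedGraph file.
#' @return A `GRanges` with a `score` metadata column (value per bp).
#' @export
read_bedgraph <- function(path) {
  f <- split_fields(path)
  if (!length(f$parts)) {
    return(GenomicRanges::GRanges(score = numeric(0)))
  }
  nf <- lengths(f$parts)
  if (any(nf < 4)) {
    stop(sprintf("line %d: bedGraph needs 4 fields", f$lineno[which(nf < 4)[1]]),
         call. = FALSE)
  }
  co <- parse_coords(f$parts, f$lineno)
  value <- suppressWarnings(as.numeric(field_col(f$parts, 4)))
  bad <- which(is.na(value) | !is.finite(value))
  if (length(bad)) {
    stop(sprintf("line %d: non-numeric value", f$lineno[bad[1]]), call. = FALSE)
  }
  bad <- which(value < 0)
  if (length(bad)) {
    stop(sprintf("line %d: negative value", f$lineno[bad[1]]), call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = field_col(f$parts, 1),
    ranges = IRanges::IRanges(start = co$start0 + 1L, end = co$end0),
    score = value)
  gr <- sorted_granges(gr)
  if (!GenomicRanges::isDisjoint(gr)) {
    stop("bedGraph contains overlapping steps", call. = FALSE)
  }
  gr
}

#' Write a signal track as bedGraph
#' @param track A `GRanges` with a `score` column.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s",
    as.character(GenomicRanges::seqnames(track)),
    GenomicRanges::start(track) - 1L,
    GenomicRanges::end(track),
    fmt_num(track$score))
  writeLines(lines, path)
  invisible(path)
}

#' Total signal mass of a track
#'
#' `sum(value * step_width)` in value*bp units; used for control rescaling
#' and conservation checks.
#' @param track A `GRanges` with a `score` column.
#' @return A number.
#' @export
signal_mass <- function(track) {
  sum(as.numeric(track$score) * GenomicRanges::width(track))
}
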