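# ROSE-style enhancer stitching: promoter-peak exclusion, gap-based merging
# of peaks into stitched enhancer domains, and signal quantification over
# constituent footprints.

#' Remove promoter-proximal peaks
#'
#' Drops every peak whose midpoint lies within `tss_window` bp of any gene
#' TSS (inclusive on both sides). `tss_window = 0` disables the filter and
#' returns the input unchanged.
#'
#' @param peaks A peak `GRanges` (see [read_narrowpeak()]).
#' @param genes A gene `GRanges` with a `tss` column (see
#'   [read_gtf_genes()]).
#' @param tss_window Half-width of the exclusion zone in bp.
#' @return The surviving peaks.
#' @export
exclude_promoter_peaks <- function(peaks, genes, tss_window = 2500) {
  stopifnot(tss_window >= 0)
  if (tss_window == 0 || !length(peaks) || !length(genes)) return(peaks)
  # midpoint in BED coordinates: floor((start0 + end0) / 2)
  mid0 <- floor((GenomicRanges::start(peaks) - 1 +
                   GenomicRanges::end(peaks)) / 2)
  mids <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(peaks),
    ranges = IRanges::IRanges(start = mid0 + 1L, width = 1L))
  tss0 <- genes$tss - 1
  zones <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(
      start = pmax(1, tss0 - tss_window + 1), end = tss0 + tss_window + 1))
  drop <- GenomicRanges::countOverlaps(mids, zones, ignore.strand = TRUE) > 0
  peaks[!drop]
}

#' Stitch peaks into enhancer domains
#'
#' Two peaks land in the same stitched region iff a chain of peaks connects
#' them with successive gaps of at most `stitch_distance` bp (gap in BED
#' coordinates: `next.start - prev.end`; overlapping or touching peaks are
#' merged first). Each input peak is a constituent of exactly one region and
#' each region spans exactly the extent of its constituents.
#'
#' @param peaks A peak `GRanges`.
#' @param stitch_distance Maximum gap in bp.
#' @return A `GRanges` of stitched regions with metadata columns
#'   `region_id`, `n_constituents` (number of original peaks),
#'   `peak_signal` (sum of constituent `signalValue`s, the quantification
#'   fallback) and `constituents` (a `GRangesList` of merged constituent
#'   footprints).
#' @export
stitch <- function(peaks, stitch_distance = 12500) {
  stopifnot(stitch_distance >= 0)
  if (!length(peaks)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      region_id = character(0), n_constituents = integer(0),
      peak_signal = numeric(0),
      constituents = GenomicRanges::GRangesList())
    return(gr)
  }
  peaks <- sorted_granges(peaks)
  regions <- GenomicRanges::reduce(
    peaks, min.gapwidth = stitch_distance + 1, ignore.strand = TRUE)
  fp <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  p2r <- GenomicRanges::findOverlaps(peaks, regions, ignore.strand = TRUE)
  f2r <- GenomicRanges::findOverlaps(fp, regions, ignore.strand = TRUE)
  n_const <- tabulate(S4Vectors::subjectHits(p2r), nbins = length(regions))
  sig <- peaks$signalValue %||% rep(0, length(peaks))
  peak_signal <- as.numeric(rowsum(
    as.numeric(sig[S4Vectors::queryHits(p2r)]),
    group = factor(S4Vectors::subjectHits(p2r),
                   levels = seq_along(regions))))
  const <- S4Vectors::split(fp[S4Vectors::queryHits(f2r)],
                            factor(S4Vectors::subjectHits(f2r),
                                   levels = seq_along(regions)))
  names(const) <- NULL
  regions$region_id <- sprintf("region_%05d", seq_along(regions))
  regions$n_constituents <- n_const
  regions$peak_signal <- peak_signal
  regions$constituents <- const
  regions
}

#' Quantify stitched regions against a signal track
#'
#' Region signal is the sum over constituent-footprint base pairs of the
#' bedGraph value (uncovered bp contribute 0). With a control track, the
#' control sum over the same footprint — rescaled by the ratio of total
#' track masses — is subtracted and the result floored at 0. Without a
#' signal track the fallback is the sum of constituent peak `signalValue`s.
#'
#' @param regions Stitched regions from [stitch()].
#' @param signal A signal `GRanges` from [read_bedgraph()], or `NULL` for
#'   the signalValue fallback.
#' @param control Optional control track (input subtraction).
#' @return `regions` with a numeric `signal` metadata column filled.
#' @export
quantify <- function(regions, signal = NULL, control = NULL) {
  if (!length(regions)) {
    regions$signal <- numeric(0)
    return(regions)
  }
  if (is.null(signal)) {
    regions$signal <- as.numeric(regions$peak_signal)
    return(regions)
  }
  s <- footprint_mass(regions, signal)
  if (!is.null(control)) {
    ratio <- signal_mass(signal) / signal_mass(control)
    s <- pmax(0, s - footprint_mass(regions, control) * ratio)
  }
  regions$signal <- s
  regions
}

# Sum of track value * covered bp over each region's constituent footprints.
footprint_mass <- function(regions, track) {
  fp <- unlist(regions$constituents)
  grp <- rep(seq_along(regions), lengths(regions$constituents))
  ov <- GenomicRanges::findOverlaps(fp, track, ignore.strand = TRUE)
  out <- numeric(length(regions))
  if (!length(ov)) return(out)
  inter <- GenomicRanges::pintersect(fp[S4Vectors::queryHits(ov)],
                                     track[S4Vectors::subjectHits(ov)])
  contrib <- as.numeric(GenomicRanges::width(inter)) *
    track$score[S4Vectors::subjectHits(ov)]
  agg <- rowsum(contrib, grp[S4Vectors::queryHits(ov)])
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
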