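# Super-enhancer calling: rank stitched regions by signal, find the
# hockey-stick cutoff (ROSE tangent criterion), flag super-enhancers and
# assign them to nearby genes.

#' Hockey-stick cutoff on a ranked signal curve
#'
#' Implements the ROSE tangent criterion by exhaustive search: sort signals
#' ascending, set the reference slope `m = (max - min) / n`, and through
#' every point `(x, s_x)` draw the line of slope `m`; the cutoff index `x*`
#' is the index minimising the number of points at or below its line — at
#' the inflection the sliding diagonal is tangent to the curve from below,
#' so almost the whole curve lies above it. Ties resolve to the largest
#' `x` (the most conservative cutoff) and the cutoff value is
#' `y* = s_{x*}`. Regions with signal strictly above `y*` are
#' super-enhancers. With all signals equal the slope is 0, every line
#' covers all points, the tie resolves to `x* = n` and no region exceeds
#' the cutoff.
#'
#' @param signals Non-negative finite signal values (n >= 2).
#' @return A list with `cutoff_index` (`x*`, on the ascending-sorted
#'   curve), `cutoff` (`y*`) and `n_super`.
#' @export
hockey_stick_cutoff <- function(signals) {
  n <- length(signals)
  stopifnot(n >= 2, all(is.finite(signals)), all(signals >= 0))
  s <- sort(signals)
  m <- (s[n] - s[1]) / n
  idx <- seq_len(n)
  counts <- integer(n)
  for (x in idx) {
    counts[x] <- sum(s <= s[x] + m * (idx - x))
  }
  x_star <- max(which(counts == min(counts)))
  list(cutoff_index = x_star, cutoff = s[x_star],
       n_super = sum(s > s[x_star]))
}

#' Call super-enhancers from quantified stitched regions
#'
#' Ranks regions by ascending signal, finds the hockey-stick cutoff and
#' flags every region with signal strictly above it. A single region cannot
#' define a curve and is flagged typical.
#'
#' @param regions Quantified regions from [quantify()] (need `signal`).
#' @return An object of class `"enhancer_table"`: a list with `regions`
#'   (the input `GRanges` sorted by ascending signal, plus `rank` and
#'   `is_super` columns), `cutoff` and `cutoff_index`.
#' @export
call_superenhancers <- function(regions) {
  if (!length(regions)) {
    stop("no regions to rank", call. = FALSE)
  }
  if (is.null(regions$signal)) {
    stop("regions are not quantified; run quantify() first", call. = FALSE)
  }
  ord <- order(regions$signal, regions$region_id)
  regions <- regions[ord]
  n <- length(regions)
  if (n == 1) {
    cut <- list(cutoff_index = 1L, cutoff = regions$signal[1])
  } else {
    cut <- hockey_stick_cutoff(regions$signal)
  }
  regions$rank <- seq_len(n)
  regions$is_super <- regions$signal > cut$cutoff
  structure(list(regions = regions,
                 cutoff = cut$cutoff,
                 cutoff_index = cut$cutoff_index),
            class = "enhancer_table")
}

#' @export
print.enhancer_table <- function(x, ...) {
  cat(sprintf(
    "Ranked enhancer table: %d regions, cutoff %.4g (rank %d), %d super\n",
    length(x$regions), x$cutoff, x$cutoff_index, sum(x$regions$is_super)))
  invisible(x)
}

#' Assign super-enhancers to genes by TSS proximity
#'
#' A gene is assigned to a super-enhancer iff its TSS lies inside the
#' region (distance 0) or within `window` bp of a region boundary. Genes
#' may hit several super-enhancers and vice versa. Per super-enhancer the
#' nearest TSS (ties: alphabetically first symbol) is flagged primary.
#'
#' @param table An `"enhancer_table"` from [call_superenhancers()].
#' @param genes A gene `GRanges` with `symbol` and `tss` columns.
#' @param window Maximum TSS-to-boundary distance in bp.
#' @param restrict_to Optional character vector of assignable symbols
#'   (e.g. a transcription-factor list).
#' @return A data.frame with columns `se_id`, `symbol`, `distance` (bp, 0
#'   if the TSS is inside the region) and `is_primary`.
#' @export
assign_genes <- function(table, genes, window = 50000, restrict_to = NULL) {
  stopifnot(window >= 0, inherits(table, "enhancer_table"))
  se <- table$regions[table$regions$is_super]
  if (!is.null(restrict_to)) genes <- genes[genes$symbol %in% restrict_to]
  empty <- data.frame(se_id = character(0), symbol = character(0),
                      distance = numeric(0), is_primary = logical(0))
  if (!length(se) || !length(genes)) return(empty)
  tss_pts <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(start = genes$tss, width = 1L))
  padded <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(se),
    ranges = IRanges::IRanges(
      start = pmax(1, GenomicRanges::start(se) - window),
      end = GenomicRanges::end(se) + window))
  ov <- GenomicRanges::findOverlaps(padded, tss_pts, ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  # distance in BED coordinates: 0 inside [s0, e0), else offset past the
  # nearest boundary
  s0 <- GenomicRanges::start(se)[qi] - 1
  e0 <- GenomicRanges::end(se)[qi]
  t0 <- genes$tss[si] - 1
  d <- ifelse(t0 >= s0 & t0 < e0, 0,
              ifelse(t0 < s0, s0 - t0, t0 - e0 + 1))
  keep <- d <= window
  out <- data.frame(se_id = se$region_id[qi][keep],
                    symbol = genes$symbol[si][keep],
                    distance = as.numeric(d[keep]),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("se_id", "symbol")]), , drop = FALSE]
  out <- out[order(out$se_id, out$distance, out$symbol), , drop = FALSE]
  out$is_primary <- !duplicated(out$se_id)
  rownames(out) <- NULL
  out
}

#' Symbols of SE-associated TFs
#' @param assignments Assignment table from [assign_genes()].
#' @return Sorted character vector of symbols with at least one assignment.
#' @export
se_associated_tfs <- function(assignments) {
  sort(unique(assignments$symbol))
}

#' Write / read a ranked super-enhancer table
#'
#' Tab-separated with header; coordinates are written 0-based half-open
#' (BED convention). `assigned_genes` is a comma-separated symbol list
#' (empty when no assignment).
#'
#' @param table An `"enhancer_table"`.
#' @param path Output path.
#' @param assignments Optional assignment table from [assign_genes()] used
#'   to fill `assigned_genes`.
#' @return The path (write) or a data.frame (read).
#' @export
write_se_table <- function(table, path, assignments = NULL) {
  r <- table$regions
  genes <- rep("", length(r))
  if (!is.null(assignments) && nrow(assignments)) {
    agg <- vapply(split(assignments$symbol, assignments$se_id),
                  function(s) paste(sort(unique(s)), collapse = ","),
                  character(1))
    hit <- match(r$region_id, names(agg))
    genes[!is.na(hit)] <- agg[hit[!is.na(hit)]]
  }
  df <- data.frame(
    region_id = r$region_id,
    chrom = as.character(GenomicRanges::seqnames(r)),
    start = GenomicRanges::start(r) - 1L,
    end = GenomicRanges::end(r),
    n_constituents = r$n_constituents,
    signal = fmt_num(r$signal, 6),
    rank = r$rank,
    is_super = ifelse(r$is_super, "TRUE", "FALSE"),
    assigned_genes = genes)
  df <- df[order(-df$rank), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_se_table
#' @export
read_se_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(assigned_genes = "character"))
}
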