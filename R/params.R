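# Shared constants and the pipeline parameter bundle.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(4L, 3L, 2L, 1L) # index map A<->T, C<->G

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameters controlling the super-enhancer and circuitry pipeline
#'
#' Bundles every tunable threshold of the analysis in one validated object.
#' Defaults follow the conventions of the tools the pipeline emulates: ROSE
#' for stitching (12.5 kb) and promoter exclusion (+/- 2.5 kb around a TSS),
#' a 50 kb proximity window for enhancer-to-gene assignment, a 500 bp
#' extension of super-enhancer regions before motif scanning, and FIMO-style
#' scanning (pseudocount 0.1, uniform background, p <= 1e-4).
#'
#' @param stitch_distance Maximum genomic gap (bp, BED convention:
#'   `next.start - prev.end`) across which adjacent peaks are merged into one
#'   stitched enhancer domain.
#' @param tss_window Half-width (bp) of the promoter exclusion zone around
#'   each TSS; peaks whose midpoint falls inside it are dropped before
#'   stitching. `0` disables promoter exclusion.
#' @param assign_window Maximum distance (bp) between a gene TSS and a
#'   super-enhancer boundary for the gene to be assigned to it.
#' @param extension Extension (bp) applied to each side of a super-enhancer
#'   region before motif scanning.
#' @param pseudocount Pseudocount mixed into PWM probabilities (as
#'   `pseudocount * background`) before log-odds scoring.
#' @param background Length-4 base composition (A, C, G, T) used as the
#'   scanning null model; normalised to sum to 1. When both strands are
#'   scanned it is symmetrised over complementary bases.
#' @param pvalue_threshold Exact p-value at or below which a scored window is
#'   reported as a motif hit.
#' @param score_bins Number of discretisation bins for the exact score
#'   distribution (dynamic programming); larger is more precise.
#' @param edge_min Minimum motif-hit count for a directed regulatory edge.
#' @param self_threshold A TF is autoregulated when its own-motif count in
#'   its extended super-enhancer region is strictly greater than this
#'   (default 2, i.e. "more than two binding motifs").
#' @param min_size,max_size Size bounds for enumerated circuitries;
#'   `max_size = NULL` means unbounded.
#' @param maximal_only If `TRUE`, occurrence counting and scoring are
#'   restricted to maximal circuitries (sensitivity-analysis mode); the
#'   default counts over all fully interconnected subsets.
#'
#' @return A list of class `"crc_params"`.
#' @export
crc_params <- function(stitch_distance = 12500,
                       tss_window = 2500,
                       assign_window = 50000,
                       extension = 500,
                       pseudocount = 0.1,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pvalue_threshold = 1e-4,
                       score_bins = 1000,
                       edge_min = 1L,
                       self_threshold = 2L,
                       min_size = 2L,
                       max_size = NULL,
                       maximal_only = FALSE) {
  stopifnot(
    stitch_distance >= 0, tss_window >= 0, assign_window >= 0,
    extension >= 0, pseudocount >= 0,
    length(background) == 4, all(is.finite(background)), all(background > 0),
    pvalue_threshold > 0, pvalue_threshold < 1,
    score_bins >= 100,
    edge_min >= 1, self_threshold >= 0, min_size >= 2,
    is.null(max_size) || max_size >= min_size
  )
  background <- as.numeric(background) / sum(background)
  names(background) <- DNA_BASES
  structure(
    list(
      stitch_distance = as.numeric(stitch_distance),
      tss_window = as.numeric(tss_window),
      assign_window = as.numeric(assign_window),
      extension = as.numeric(extension),
      pseudocount = as.numeric(pseudocount),
      background = background,
      pvalue_threshold = as.numeric(pvalue_threshold),
      score_bins = as.integer(score_bins),
      edge_min = as.integer(edge_min),
      self_threshold = as.numeric(self_threshold),
      min_size = as.integer(min_size),
      max_size = if (is.null(max_size)) NULL else as.integer(max_size),
      maximal_only = isTRUE(maximal_only)
    ),
    class = "crc_params"
  )
}

#' @export
print.crc_params <- function(x, ...) {
  cat("CRC pipeline parameters:\n")
  for (nm in setdiff(names(x), "background")) {
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  cat(sprintf("  %-18s %s\n", "background",
              paste(sprintf("%s=%.3f", names(x$background), x$background),
                    collapse = " ")))
  invisible(x)
}

# Symmetrise a base composition over complementary pairs; appropriate when
# both strands are scanned with one null model.
symmetrize_background <- function(bg) {
  out <- (bg + bg[DNA_COMPLEMENT]) / 2
  names(out) <- DNA_BASES
  out / sum(out)
}

# Map a DNA string to integer codes 1..4 (A,C,G,T); anything else -> NA.
encode_dna <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
}

decode_dna <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- DNA_BASES[codes[ok]]
  paste0(out, collapse = "")
}

revcomp_codes <- function(codes) {
  out <- rev(codes)
  ok <- !is.na(out)
  out[ok] <- DNA_COMPLEMENT[out[ok]]
  out
}

# Canonical numeric formatting for the tab-delimited writers (byte-stable).
fmt_num <- function(x, digits = 4) {
  sprintf(paste0("%.", digits, "f"), x)
}
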