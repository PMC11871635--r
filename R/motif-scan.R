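# FIMO-style PWM scanning: log-odds scoring in bits, exact p-values by
# position-wise convolution of a discretised score distribution, stranded
# hit calling over extended super-enhancer sequences.

#' Extend genomic regions on both sides
#'
#' Adds `extension` bp to each side, clipping at position 1 and at the
#' chromosome length when known.
#'
#' @param regions A `GRanges`.
#' @param extension Extension in bp (>= 0).
#' @param seqlens Optional named vector of chromosome lengths; defaults to
#'   `seqlengths(regions)` where set.
#' @return The extended `GRanges`.
#' @export
extend_regions <- function(regions, extension = 500, seqlens = NULL) {
  stopifnot(extension >= 0)
  if (is.null(seqlens)) seqlens <- GenomeInfoDb::seqlengths(regions)
  new_start <- pmax(1L, GenomicRanges::start(regions) - as.integer(extension))
  new_end <- GenomicRanges::end(regions) + as.integer(extension)
  lens <- seqlens[as.character(GenomicRanges::seqnames(regions))]
  has_len <- !is.na(lens)
  new_end[has_len] <- pmin(new_end[has_len], as.integer(lens[has_len]))
  GenomicRanges::ranges(regions) <- IRanges::IRanges(new_start, new_end)
  regions
}

#' Log-odds score matrix of a PWM (bits)
#'
#' `entry(j, b) = log2( ((p[j,b] + pc * bg[b]) / (1 + pc)) / bg[b] )`:
#' the PWM is mixed with `pc` pseudocounts of background before scoring.
#'
#' @param pwm A `"pwm"` object.
#' @param background Length-4 base composition; must be strictly positive.
#' @param pseudocount Pseudocount weight `pc`.
#' @return A `width x 4` numeric matrix in bits.
#' @export
log_odds_matrix <- function(pwm, background = rep(0.25, 4),
                            pseudocount = 0.1) {
  if (any(background <= 0)) {
    stop("background entries must be strictly positive", call. = FALSE)
  }
  background <- background / sum(background)
  bgm <- matrix(background, nrow = pwm_width(pwm), ncol = 4, byrow = TRUE)
  m <- log2(((pwm$probs + pseudocount * bgm) / (1 + pseudocount)) / bgm)
  dimnames(m) <- list(NULL, DNA_BASES)
  m
}

#' Exact discretised distribution of window scores under the background
#'
#' Each matrix cell is mapped to a non-negative integer on a common scale
#' (about `bins` steps across the full score range) and the distribution of
#' the integer window score under the i.i.d. background model is built by
#' position-wise convolution. Tail probabilities are exact on the integer
#' scale; real-score queries carry a discretisation error of order
#' `width / (2 * scale)`.
#'
#' @param score_matrix A `width x 4` finite score matrix
#'   (see [log_odds_matrix()]).
#' @param background Length-4 base composition.
#' @param bins Number of discretisation bins (>= 100).
#' @return A list of class `"score_dist"` with elements `ints` (integer
#'   matrix), `tail` (tail probabilities indexed by integer score),
#'   `scale`, `min_score`, `max_int` and `int_n` (per-row integer value of a
#'   zero-bit contribution, used for N bases).
#' @export
score_distribution <- function(score_matrix, background = rep(0.25, 4),
                               bins = 1000) {
  m <- as.matrix(score_matrix)
  stopifnot(ncol(m) == 4, all(is.finite(m)), bins >= 100)
  background <- background / sum(background)
  rmin <- apply(m, 1, min)
  rmax <- apply(m, 1, max)
  rng <- sum(rmax) - sum(rmin)
  scale <- if (rng > 0) bins / rng else 1
  ints <- round((m - rmin) * scale)
  storage.mode(ints) <- "integer"
  max_int <- sum(apply(ints, 1, max))
  pdf <- numeric(max_int + 1)
  pdf[1] <- 1
  for (j in seq_len(nrow(m))) {
    new <- numeric(max_int + 1)
    for (b in 1:4) {
      k <- ints[j, b]
      n <- max_int + 1 - k
      new[(k + 1):(k + n)] <- new[(k + 1):(k + n)] + pdf[1:n] * background[b]
    }
    pdf <- new
  }
  tail <- rev(cumsum(rev(pdf)))
  structure(list(ints = ints,
                 tail = tail,
                 scale = scale,
                 min_score = sum(rmin),
                 max_int = max_int,
                 int_n = as.integer(round((0 - rmin) * scale))),
            class = "score_dist")
}

# p-value of integer window scores (vectorised); scores outside the
# achievable range clamp to 1 (below) or 0 (above).
pvalue_from_int <- function(dist, s) {
  p <- numeric(length(s))
  lo <- s <= 0
  hi <- s > dist$max_int
  mid <- !lo & !hi
  p[lo] <- 1
  p[hi] <- 0
  p[mid] <- dist$tail[s[mid] + 1L]
  p
}

#' Tail probability of a real-valued score threshold
#'
#' `P(window score >= t)` under the background model, evaluated on the
#' discretised distribution.
#'
#' @param dist A `"score_dist"`.
#' @param t Score threshold (bits).
#' @return A probability.
#' @export
tail_probability <- function(dist, t) {
  s <- as.integer(ceiling(round((t - dist$min_score) * dist$scale, 9)))
  pvalue_from_int(dist, s)
}

# Scan integer-coded sequence with one oriented integer/real matrix pair.
# codes: 1..4 or NA (N); returns data.frame(start, score, pvalue).
scan_codes_oriented <- function(codes, real_m, int_m, int_n, dist, threshold) {
  w <- nrow(real_m)
  L <- length(codes)
  if (L < w) {
    return(data.frame(start = integer(0), score = numeric(0),
                      pvalue = numeric(0)))
  }
  nw <- L - w + 1L
  si <- integer(nw)
  sr <- numeric(nw)
  for (j in seq_len(w)) {
    b <- codes[j:(j + nw - 1L)]
    addi <- unname(int_m[j, ][b])
    addr <- unname(real_m[j, ][b])
    nas <- is.na(b)
    if (any(nas)) {
      addi[nas] <- int_n[j]
      addr[nas] <- 0
    }
    si <- si + addi
    sr <- sr + addr
  }
  pv <- pvalue_from_int(dist, si)
  keep <- which(pv <= threshold)
  data.frame(start = keep, score = sr[keep], pvalue = pv[keep])
}

# Precompute everything scanning needs for one PWM under fixed params.
scan_model <- function(pwm, params) {
  bg <- symmetrize_background(params$background)
  lo <- log_odds_matrix(pwm, bg, params$pseudocount)
  dist <- score_distribution(lo, bg, params$score_bins)
  w <- nrow(lo)
  # reverse-complement orientation shares the distribution exactly: its
  # integer matrix is a row/column permutation of the forward one and the
  # background is complement-symmetric
  lo_rc <- lo[rev(seq_len(w)), DNA_COMPLEMENT, drop = FALSE]
  int_rc <- dist$ints[rev(seq_len(w)), DNA_COMPLEMENT, drop = FALSE]
  list(pwm = pwm, lo = lo, lo_rc = lo_rc, int_rc = int_rc,
       int_n_rc = rev(dist$int_n), dist = dist)
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window on both strands is scored; windows whose exact p-value is at
#' or below `params$pvalue_threshold` are reported. Overlapping hits are all
#' kept (no masking). N bases contribute zero bits. A minus-strand hit is
#' reported at the forward-strand (leftmost) coordinate of its window.
#'
#' @param sequence A character string (or `DNAString`) over A, C, G, T, N.
#' @param pwm A `"pwm"` object.
#' @param params A [crc_params()] object (uses `pseudocount`, `background`,
#'   `pvalue_threshold`, `score_bins`).
#' @return A data.frame with columns `motif_id`, `start` (1-based), `strand`,
#'   `score` (bits), `pvalue`, ordered by `start` then strand.
#' @export
scan_sequence <- function(sequence, pwm, params = crc_params()) {
  codes <- encode_dna(as.character(sequence))
  model <- scan_model(pwm, params)
  scan_codes_model(codes, model, params$pvalue_threshold)
}

scan_codes_model <- function(codes, model, threshold) {
  plus <- scan_codes_oriented(codes, model$lo, model$dist$ints,
                              model$dist$int_n, model$dist, threshold)
  minus <- scan_codes_oriented(codes, model$lo_rc, model$int_rc,
                               model$int_n_rc, model$dist, threshold)
  if (nrow(plus)) plus$strand <- "+"
  else plus$strand <- character(0)
  if (nrow(minus)) minus$strand <- "-"
  else minus$strand <- character(0)
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out <- data.frame(motif_id = rep(model$pwm$motif_id, nrow(out)),
                    out, row.names = NULL)
  out
}

#' Scan extended super-enhancer regions with a set of motifs
#'
#' Extracts the sequence of each (already extended) region from the genome
#' and scans it with every PWM on both strands.
#'
#' @param regions A `GRanges` of regions to scan; must carry a `region_id`
#'   metadata column.
#' @param genome A `DNAStringSet` (see [read_genome()]).
#' @param pwms A list of `"pwm"` objects.
#' @param params A [crc_params()] object.
#' @return A data.frame with columns `motif_id`, `tf`, `region_id`, `start`
#'   (1-based within the region sequence), `strand`, `score`, `pvalue`.
#' @export
scan_regions <- function(regions, genome, pwms, params = crc_params()) {
  stopifnot(!is.null(regions$region_id))
  models <- lapply(pwms, scan_model, params = params)
  out <- list()
  for (i in seq_along(regions)) {
    chrom <- as.character(GenomicRanges::seqnames(regions[i]))
    if (!chrom %in% names(genome)) {
      stop(sprintf("chromosome '%s' absent from genome", chrom),
           call. = FALSE)
    }
    seq_i <- as.character(Biostrings::subseq(
      genome[[chrom]], GenomicRanges::start(regions[i]),
      GenomicRanges::end(regions[i])))
    codes <- encode_dna(seq_i)
    for (model in models) {
      h <- scan_codes_model(codes, model, params$pvalue_threshold)
      if (nrow(h)) {
        h$tf <- model$pwm$tf_symbol
        h$region_id <- regions$region_id[i]
        out[[length(out) + 1]] <- h
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif_id = character(0), tf = character(0),
                      region_id = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      pvalue = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[, c("motif_id", "tf", "region_id", "start", "strand",
          "score", "pvalue")]
}

#' Count motif hits per (source TF, target TF) pair
#'
#' The count for (a, b) is the total number of hits of TF a's motif across
#' all extended super-enhancer regions assigned to TF b — both strands,
#' overlapping hits counted individually. Every ordered pair over the given
#' TF universes is present in the result (missing combinations count 0).
#'
#' @param hits Hit table from [scan_regions()] (needs `tf`, `region_id`).
#' @param assignments Assignment table from [assign_genes()] (needs `se_id`,
#'   `symbol`).
#' @param source_tfs Source TF universe; defaults to TFs present in `hits`.
#' @param target_tfs Target TF universe; defaults to TFs present in
#'   `assignments`.
#' @return A data.frame with columns `source_tf`, `target_tf`, `count`.
#' @export
count_hits <- function(hits, assignments,
                       source_tfs = NULL, target_tfs = NULL) {
  source_tfs <- sort(unique(source_tfs %||% hits$tf))
  target_tfs <- sort(unique(target_tfs %||% assignments$symbol))
  grid <- expand.grid(source_tf = source_tfs, target_tf = target_tfs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$count <- integer(nrow(grid))
  if (nrow(hits) && nrow(assignments)) {
    # a region may be assigned to several TFs; hits count toward each
    joined <- merge(hits, assignments[, c("se_id", "symbol")],
                    by.x = "region_id", by.y = "se_id")
    if (nrow(joined)) {
      tab <- table(joined$tf, joined$symbol)
      idx_s <- match(grid$source_tf, rownames(tab))
      idx_t <- match(grid$target_tf, colnames(tab))
      ok <- !is.na(idx_s) & !is.na(idx_t)
      grid$count[ok] <- as.integer(tab[cbind(idx_s[ok], idx_t[ok])])
    }
  }
  grid[order(grid$source_tf, grid$target_tf), , drop = FALSE]
}

#' Estimate a 0-order background from sequences
#'
#' Counts A/C/G/T over the sequences and symmetrises complementary bases
#' (appropriate for double-stranded scanning). N bases are ignored.
#'
#' @param sequences Character vector (or `DNAStringSet`) of sequences.
#' @return A named length-4 frequency vector.
#' @export
estimate_background <- function(sequences) {
  codes <- unlist(lapply(as.character(sequences), encode_dna))
  codes <- codes[!is.na(codes)]
  if (!length(codes)) {
    return(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  }
  counts <- tabulate(codes, nbins = 4)
  symmetrize_background(counts / sum(counts))
}
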