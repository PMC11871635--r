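# Independent brute-force oracles used across the suite. These deliberately
# take different code paths from the implementation (igraph components
# instead of reduce(), rank statistics instead of the sliding-line loop,
# exhaustive word enumeration instead of the DP convolution).

# O(n^2) transitive-closure stitching oracle; returns BED footprints.
oracle_stitch <- function(peaks, d) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   s = GenomicRanges::start(peaks) - 1L,
                   e = GenomicRanges::end(peaks))
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    g1 <- outer(sub$s, sub$e, "-") # g1[i,j] = s_i - e_j
    adj <- (g1 <= d) & (t(g1) <= d)
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    for (k in unique(comp)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, s = min(sub$s[comp == k]), e = max(sub$e[comp == k]))
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

regions_to_bed <- function(regions) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   s = GenomicRanges::start(regions) - 1L,
                   e = GenomicRanges::end(regions))
  df <- df[order(df$chrom, df$s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Tangent-line cutoff via a rank statistic: a point is at or below the line
# through (x, s_x) iff s_i - m*i <= s_x - m*x, so the count below equals the
# max-tie rank of the detrended value.
oracle_hockey <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  m <- (s[n] - s[1]) / n
  detr <- s - m * seq_len(n)
  below <- rank(detr, ties.method = "max")
  x <- max(which(below == min(below)))
  list(cutoff_index = x, cutoff = s[x])
}

# All-pairs promoter-exclusion oracle on BED midpoints.
oracle_promoter_filter <- function(peaks, genes, window) {
  mid0 <- floor((GenomicRanges::start(peaks) - 1 +
                   GenomicRanges::end(peaks)) / 2)
  pc <- as.character(GenomicRanges::seqnames(peaks))
  gc <- as.character(GenomicRanges::seqnames(genes))
  keep <- vapply(seq_along(peaks), function(i) {
    !any(gc == pc[i] & abs((genes$tss - 1) - mid0[i]) <= window)
  }, logical(1))
  peaks[keep]
}

# Per-bp quantification oracle: materialise the coverage vector.
oracle_region_signal <- function(regions, track) {
  cov <- list()
  tc <- as.character(GenomicRanges::seqnames(track))
  vapply(seq_along(regions), function(i) {
    fp <- regions$constituents[[i]]
    total <- 0
    for (j in seq_along(fp)) {
      ch <- as.character(GenomicRanges::seqnames(fp[j]))
      for (pos in GenomicRanges::start(fp[j]):GenomicRanges::end(fp[j])) {
        sel <- tc == ch & GenomicRanges::start(track) <= pos &
          GenomicRanges::end(track) >= pos
        if (any(sel)) total <- total + track$score[sel][1]
      }
    }
    total
  }, numeric(1))
}

# All-pairs SE-to-gene assignment oracle (BED distance convention).
oracle_assign <- function(table, genes, window) {
  se <- table$regions[table$regions$is_super]
  out <- list()
  for (i in seq_along(se)) {
    for (j in seq_along(genes)) {
      if (as.character(GenomicRanges::seqnames(se[i])) !=
          as.character(GenomicRanges::seqnames(genes[j]))) next
      s0 <- GenomicRanges::start(se[i]) - 1
      e0 <- GenomicRanges::end(se[i])
      t0 <- genes$tss[j] - 1
      d <- if (t0 >= s0 && t0 < e0) 0
           else if (t0 < s0) s0 - t0 else t0 - e0 + 1
      if (d <= window) {
        out[[length(out) + 1]] <- data.frame(
          se_id = se$region_id[i], symbol = genes$symbol[j], distance = d)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(se_id = character(0), symbol = character(0),
                      distance = numeric(0)))
  }
  out <- do.call(rbind, out)
  out[order(out$se_id, out$distance, out$symbol), , drop = FALSE]
}

# Exhaustive enumeration over all 4^w words: real and integer window scores
# under the (already discretised) integer matrix of a score_dist.
oracle_word_scores <- function(lo, dist, background = rep(0.25, 4)) {
  w <- nrow(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))[, w:1, drop = FALSE]
  real <- rowSums(matrix(lo[cbind(rep(seq_len(w), each = nrow(words)),
                                  as.vector(words))],
                         nrow = nrow(words)))
  ints <- rowSums(matrix(dist$ints[cbind(rep(seq_len(w), each = nrow(words)),
                                         as.vector(words))],
                         nrow = nrow(words)))
  prob <- apply(words, 1, function(wd) prod(background[wd]))
  list(real = real, ints = ints, prob = prob)
}

# Brute-force power-set circuitry enumeration over autoregulated nodes.
oracle_circuitries <- function(counts, edge_min, self_threshold,
                               min_size = 2) {
  tfs <- rownames(counts)
  auto <- tfs[diag(counts) > self_threshold]
  keys <- character(0)
  if (length(auto) >= min_size) {
    for (k in min_size:length(auto)) {
      if (k > length(auto)) break
      combs <- utils::combn(auto, k, simplify = FALSE)
      for (S in combs) {
        ok <- TRUE
        for (a in S) for (b in S) {
          if (a != b && counts[a, b] < edge_min) ok <- FALSE
        }
        if (ok) keys <- c(keys, paste(sort(S), collapse = ","))
      }
    }
  }
  sort(keys)
}

# Random peak GRanges on a shared coordinate system.
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000,
                         width_range = c(50, 400), signal_max = 50) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  start0 <- sample.int(max_pos, n, replace = TRUE) - 1L
  GenomicRanges::GRanges(
    seqnames = sample(chroms, n, replace = TRUE),
    ranges = IRanges::IRanges(start0 + 1L, start0 + w),
    strand = "*",
    name = sprintf("p%04d", seq_len(n)), score = rep(0, n),
    signalValue = stats::runif(n, 0, signal_max),
    pValue = rep(-1, n), qValue = rep(-1, n), peak = rep(-1L, n))
}

random_pwm <- function(w, id = "m1", tf = "TFX", concentration = 2) {
  p <- matrix(stats::rgamma(4 * w, shape = concentration), nrow = w)
  p <- p / rowSums(p)
  pwm_record(id, tf, p)
}

random_sequence <- function(len, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
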