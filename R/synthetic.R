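# Synthetic epigenome generator: a small random genome with TF genes, a
# planted fully interconnected autoregulatory circuit carried by clustered
# high-signal peaks (the planted super-enhancers), decoy TFs with near-miss
# structure, background peaks, and a machine-readable truth file.

#' Configuration of the synthetic epigenome
#'
#' Defaults describe the validation conditions used throughout: a 20-TF
#' genome with a planted fully interconnected 5-TF circuit (each planted
#' super-enhancer carries >= 3 embedded instances of every circuit member's
#' motif, so every member passes the strict "more than two" autoregulation
#' rule), near-miss decoys that probe the rule's boundaries, and clearly
#' separated log-normal signal levels.
#'
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output files.
#' @param n_chroms,chrom_len Number and length (bp) of chromosomes.
#' @param n_tf_genes Total TF genes (>= k_core + pair + trio decoys).
#' @param k_core Size of the planted circuit.
#' @param motif_width PWM width; must satisfy `0.25^width <=
#'   scan$pvalue_threshold` so a consensus instance is detectable.
#' @param self_motif_copies Instances of each core member's motif embedded
#'   per planted super-enhancer (>= 3).
#' @param n_background_peaks Low-signal singleton peaks scattered away from
#'   the enhancer clusters.
#' @param se_peak_cluster Peaks per planted enhancer cluster.
#' @param peak_width_range,cluster_gap_range Constituent peak widths and
#'   intra-cluster gaps (bp); gaps stay far below the stitch distance.
#' @param cluster_offset_range Distance (bp) from the host TSS to the
#'   cluster start; beyond the promoter-exclusion window, within the
#'   assignment window.
#' @param gene_length_range,gene_jitter Gene body lengths and placement
#'   jitter around evenly spaced slots (genes stay >= 50 kb apart).
#' @param signal_high,signal_low Log-normal (meanlog, sdlog) per-bp signal
#'   for planted cluster constituents vs background/singleton peaks; the
#'   high median must exceed the low 99th percentile.
#' @param decoy_signal_factor Scale applied to decoy-cluster signal so
#'   decoy clusters are still super-enhancers but weaker than planted ones.
#' @param n_pair_decoys,n_trio_decoys Decoy structure sizes: a pair with
#'   full cross-wiring but exactly `self_threshold` self-motifs (fails the
#'   strict rule), and a trio with one directed edge removed (fails full
#'   interconnection at size 3).
#' @param gc_content Genome GC fraction.
#' @param scan A [crc_params()] object; its scanning parameters are used to
#'   scrub and verify the planted truth so that planted hit counts are
#'   exact at these settings.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L,
                             chrom_len = 1800000L,
                             n_tf_genes = 20L,
                             k_core = 5L,
                             motif_width = 8L,
                             self_motif_copies = 3L,
                             n_background_peaks = 150L,
                             se_peak_cluster = 5L,
                             peak_width_range = c(300L, 800L),
                             cluster_gap_range = c(800L, 2500L),
                             cluster_offset_range = c(3000L, 5000L),
                             gene_length_range = c(8000L, 12000L),
                             gene_jitter = 5000L,
                             signal_high = c(meanlog = 4, sdlog = 0.3),
                             signal_low = c(meanlog = 1, sdlog = 0.3),
                             decoy_signal_factor = 0.35,
                             n_pair_decoys = 2L,
                             n_trio_decoys = 3L,
                             gc_content = 0.41,
                             scan = crc_params()) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len),
              n_tf_genes = as.integer(n_tf_genes),
              k_core = as.integer(k_core),
              motif_width = as.integer(motif_width),
              self_motif_copies = as.integer(self_motif_copies),
              n_background_peaks = as.integer(n_background_peaks),
              se_peak_cluster = as.integer(se_peak_cluster),
              peak_width_range = as.integer(peak_width_range),
              cluster_gap_range = as.integer(cluster_gap_range),
              cluster_offset_range = as.integer(cluster_offset_range),
              gene_length_range = as.integer(gene_length_range),
              gene_jitter = as.integer(gene_jitter),
              signal_high = signal_high, signal_low = signal_low,
              decoy_signal_factor = as.numeric(decoy_signal_factor),
              n_pair_decoys = as.integer(n_pair_decoys),
              n_trio_decoys = as.integer(n_trio_decoys),
              gc_content = as.numeric(gc_content),
              scan = scan)
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_len >= 2e5,
            cfg$k_core >= 2, cfg$motif_width >= 4,
            cfg$self_motif_copies >= 3,
            cfg$se_peak_cluster >= 2,
            cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$n_pair_decoys %in% c(0L, 2L),
            cfg$n_trio_decoys %in% c(0L, 3L),
            inherits(scan, "crc_params"))
  if (cfg$k_core + cfg$n_pair_decoys + cfg$n_trio_decoys > cfg$n_tf_genes) {
    stop("n_tf_genes must cover the core set plus decoy structures",
         call. = FALSE)
  }
  if (0.25^cfg$motif_width > cfg$scan$pvalue_threshold) {
    stop(sprintf(paste0("motif_width %d is too small for detection at ",
                        "p <= %g; widen the motif or relax the threshold"),
                 cfg$motif_width, cfg$scan$pvalue_threshold), call. = FALSE)
  }
  if (stats::qlnorm(0.5, cfg$signal_high["meanlog"],
                    cfg$signal_high["sdlog"]) <=
      stats::qlnorm(0.99, cfg$signal_low["meanlog"],
                    cfg$signal_low["sdlog"])) {
    stop("signal_high median must exceed the signal_low 99th percentile",
         call. = FALSE)
  }
  if (cfg$cluster_gap_range[2] >= cfg$scan$stitch_distance) {
    stop("intra-cluster gaps must be below the stitch distance",
         call. = FALSE)
  }
  if (cfg$cluster_offset_range[1] <= cfg$scan$tss_window) {
    stop("cluster_offset_range must start beyond the promoter window",
         call. = FALSE)
  }
  genes_per_chrom <- ceiling(cfg$n_tf_genes / cfg$n_chroms)
  spacing <- cfg$chrom_len / (genes_per_chrom + 1)
  if (spacing < 90000) {
    stop("chromosomes too short for the requested gene count (need >= 90 kb slots)",
         call. = FALSE)
  }
  # background peaks are singletons: each needs stitch_distance of clearance
  min_gap <- cfg$scan$stitch_distance + 1000
  n_clustered <- cfg$k_core + cfg$n_pair_decoys + cfg$n_trio_decoys
  free <- cfg$n_chroms * (cfg$chrom_len - 40000) -
    n_clustered * (20000 + 2 * min_gap) -
    (cfg$n_tf_genes - n_clustered) * (500 + 2 * min_gap)
  if (free < cfg$n_background_peaks *
        (min_gap + cfg$peak_width_range[2] + 2000)) {
    stop("chromosomes too short for that many singleton background peaks",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

hamming <- function(a, b) sum(a != b)

#' Generate mutually dissimilar PWMs, one per TF
#'
#' Consensus words are drawn at random subject to pairwise Hamming distance
#' >= width/2 — also against every reverse complement and each word's own
#' reverse complement, so hits are unambiguous on both strands. Each column
#' puts probability 0.9 on the consensus base and spreads the rest evenly.
#'
#' @param config A [synthetic_config()].
#' @return Named list of `"pwm"` objects, one per TF symbol (`TF01`, ...).
#' @export
generate_pwms <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  w <- config$motif_width
  n <- config$n_tf_genes
  min_d <- w / 2
  consensi <- list()
  tries <- 0
  while (length(consensi) < n) {
    tries <- tries + 1
    if (tries > 5000) {
      stop("could not draw dissimilar consensus words; increase motif_width",
           call. = FALSE)
    }
    cand <- sample.int(4L, w, replace = TRUE)
    if (hamming(cand, revcomp_codes(cand)) < min_d) next
    ok <- all(vapply(consensi, function(e) {
      hamming(cand, e) >= min_d && hamming(cand, revcomp_codes(e)) >= min_d
    }, logical(1)))
    if (ok) consensi[[length(consensi) + 1]] <- cand
  }
  symbols <- sprintf("TF%02d", seq_len(n))
  pwms <- vector("list", n)
  for (i in seq_len(n)) {
    probs <- matrix(0.1 / 3, nrow = w, ncol = 4)
    probs[cbind(seq_len(w), consensi[[i]])] <- 0.9
    pwms[[i]] <- pwm_record(paste0(symbols[i], "_motif"), symbols[i], probs)
  }
  names(pwms) <- symbols
  pwms
}

# One consensus-sampled motif instance: per column the argmax base with
# probability 0.9, otherwise a draw from the column distribution.
sample_pwm_instance <- function(pwm, pure = FALSE) {
  cons <- apply(pwm$probs, 1, which.max)
  if (pure) return(as.integer(cons))
  out <- integer(length(cons))
  for (j in seq_along(cons)) {
    out[j] <- if (stats::runif(1) < 0.9) cons[j]
              else sample.int(4L, 1, prob = pwm$probs[j, ])
  }
  out
}

# Planted motif content of one host cluster: named copy counts per source
# TF motif, as dictated by the host's role.
planted_content <- function(host, roles, config) {
  core <- roles$core
  if (host %in% core) {
    return(stats::setNames(rep(config$self_motif_copies, length(core)), core))
  }
  if (host %in% roles$pair) {
    other <- setdiff(roles$pair, host)
    out <- stats::setNames(c(config$scan$self_threshold, 3L), c(host, other))
    return(out)
  }
  if (host %in% roles$trio) {
    out <- stats::setNames(rep(3L, length(roles$trio)), roles$trio)
    if (host == roles$missing_edge[["to"]]) {
      out <- out[names(out) != roles$missing_edge[["from"]]]
    }
    return(out)
  }
  stats::setNames(integer(0), character(0))
}

# Scan every cluster neighbourhood with every motif; returns absolute-
# coordinate hits (data.frame: motif_tf, host, chrom, start, end, strand).
scan_clusters <- function(genome_codes, clusters, models, threshold, pad) {
  out <- list()
  for (ci in seq_len(nrow(clusters))) {
    ch <- clusters$chrom[ci]
    lo <- max(1L, clusters$start[ci] - pad)
    hi <- min(length(genome_codes[[ch]]), clusters$end[ci] + pad)
    codes <- genome_codes[[ch]][lo:hi]
    for (model in models) {
      h <- scan_codes_model(codes, model, threshold)
      if (nrow(h)) {
        w <- pwm_width(model$pwm)
        out[[length(out) + 1]] <- data.frame(
          motif_tf = model$pwm$tf_symbol, host = clusters$host[ci],
          chrom = ch, start = lo + h$start - 1L,
          end = lo + h$start - 2L + w, strand = h$strand)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif_tf = character(0), host = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

#' Generate the complete synthetic input set
#'
#' Writes `genome.fa`, `genes.gtf`, `peaks.narrowPeak`, `signal.bedGraph`,
#' `motifs.meme`, `tf_list.txt` and `truth.json` into `out_dir`. The
#' genome is i.i.d. at the configured GC content except inside enhancer-
#' cluster neighbourhoods, which are made motif-clean: after embedding the
#' planted instances, any further window that scores at the scan threshold
#' is re-sampled away, and any planted instance that fails to score is
#' re-drawn — so the planted placements are exactly the motif hits the
#' scanner reports at the configured settings, and the truth file is exact.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, the file paths, and the `truth`
#'   list (also serialised as `truth.json`).
#' @export
plant_epigenome <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pwms <- generate_pwms(config)           # seeds with config$seed
  set.seed(config$seed + 1L)              # independent stream for the rest
  w <- config$motif_width
  symbols <- names(pwms)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  gc <- config$gc_content
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  genome_codes <- lapply(chroms, function(ch) {
    sample.int(4L, config$chrom_len, replace = TRUE, prob = base_prob)
  })
  names(genome_codes) <- chroms

  # --- roles ---------------------------------------------------------------
  core <- sort(sample(symbols, config$k_core))
  rest <- setdiff(symbols, core)
  pair <- if (config$n_pair_decoys) sort(sample(rest, 2)) else character(0)
  rest <- setdiff(rest, pair)
  trio <- if (config$n_trio_decoys) sort(sample(rest, 3)) else character(0)
  singleton <- setdiff(rest, trio)
  missing_edge <- if (length(trio)) {
    c(from = trio[2], to = trio[3])
  } else c(from = NA_character_, to = NA_character_)
  roles <- list(core = core, pair = pair, trio = trio,
                singleton = singleton, missing_edge = missing_edge)
  clustered <- c(core, pair, trio)

  # --- gene placement (slots with jitter; >= 50 kb apart) ------------------
  genes_per_chrom <- ceiling(config$n_tf_genes / config$n_chroms)
  slot <- config$chrom_len / (genes_per_chrom + 1)
  gene_df <- data.frame(symbol = symbols, stringsAsFactors = FALSE)
  gene_df$chrom <- chroms[((seq_len(config$n_tf_genes) - 1) %/%
                             genes_per_chrom) + 1]
  slot_idx <- ((seq_len(config$n_tf_genes) - 1) %% genes_per_chrom) + 1
  gene_df$start <- as.integer(round(slot_idx * slot +
    stats::runif(config$n_tf_genes, -config$gene_jitter,
                 config$gene_jitter)))
  gene_df$length <- as.integer(round(stats::runif(
    config$n_tf_genes, config$gene_length_range[1],
    config$gene_length_range[2])))
  gene_df$end <- gene_df$start + gene_df$length - 1L
  gene_df$strand <- sample(c("+", "-"), config$n_tf_genes, replace = TRUE)
  gene_df$tss <- ifelse(gene_df$strand == "-", gene_df$end, gene_df$start)
  genes <- gene_granges(gene_df$chrom, gene_df$start, gene_df$end,
                        gene_df$strand, gene_df$symbol, gene_df$symbol)

  # --- enhancer clusters ---------------------------------------------------
  peaks <- list()
  clusters <- list()
  for (h in clustered) {
    gi <- match(h, gene_df$symbol)
    anchor <- gene_df$tss[gi] +
      as.integer(round(stats::runif(1, config$cluster_offset_range[1],
                                    config$cluster_offset_range[2])))
    widths <- as.integer(round(stats::runif(config$se_peak_cluster,
                                            config$peak_width_range[1],
                                            config$peak_width_range[2])))
    gaps <- as.integer(round(stats::runif(config$se_peak_cluster - 1,
                                          config$cluster_gap_range[1],
                                          config$cluster_gap_range[2])))
    starts <- anchor + cumsum(c(0L, widths[-length(widths)] + gaps))
    ends <- starts + widths - 1L
    decoy <- h %in% c(pair, trio)
    vals <- stats::rlnorm(config$se_peak_cluster,
                          config$signal_high["meanlog"],
                          config$signal_high["sdlog"]) *
      if (decoy) config$decoy_signal_factor else 1
    peaks[[h]] <- data.frame(chrom = gene_df$chrom[gi], start = starts,
                             end = ends, value = vals, kind = "cluster",
                             host = h, stringsAsFactors = FALSE)
    clusters[[h]] <- data.frame(host = h, chrom = gene_df$chrom[gi],
                                start = starts[1], end = ends[length(ends)],
                                stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, clusters)

  # --- singleton decoy peaks at non-clustered TFs --------------------------
  for (h in singleton) {
    gi <- match(h, gene_df$symbol)
    st <- gene_df$tss[gi] + 4000L
    peaks[[h]] <- data.frame(chrom = gene_df$chrom[gi], start = st,
                             end = st + 499L,
                             value = stats::rlnorm(
                               1, config$signal_low["meanlog"],
                               config$signal_low["sdlog"]),
                             kind = "singleton", host = h,
                             stringsAsFactors = FALSE)
  }

  # --- background peaks: low-signal singletons, each clear of every other
  # peak by more than the stitch distance so they never form regions --------
  min_gap <- as.integer(config$scan$stitch_distance + 1000)
  existing <- do.call(rbind, lapply(peaks, function(p) {
    p[, c("chrom", "start", "end")]
  }))
  forbidden <- lapply(chroms, function(ch) {
    ei <- existing$chrom == ch
    IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, existing$start[ei] - min_gap),
      end = existing$end[ei] + min_gap))
  })
  names(forbidden) <- chroms
  quota <- floor(config$n_background_peaks / config$n_chroms)
  quota <- rep(quota, config$n_chroms)
  extra <- config$n_background_peaks - sum(quota)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  bg_peaks <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    q <- quota[ci]
    if (q == 0) next
    lo <- 20000L
    hi <- config$chrom_len - 20000L
    # evenly spaced jittered anchors keep the required clearance feasible
    step <- (hi - lo) / q
    pos <- as.integer(round(lo + (seq_len(q) - 1) * step +
                              stats::runif(q, 0, step / 3)))
    widths <- as.integer(round(stats::runif(q, config$peak_width_range[1],
                                            config$peak_width_range[2])))
    prev_end <- -1e9
    for (i in seq_len(q)) {
      st <- max(pos[i], as.integer(prev_end + min_gap))
      repeat {
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(st, st + widths[i] - 1L), forbidden[[ch]])
        if (!length(ov)) break
        st <- max(IRanges::end(forbidden[[ch]])[
          S4Vectors::subjectHits(ov)]) + 1L
        st <- max(st, as.integer(prev_end + min_gap))
      }
      if (st + widths[i] - 1L > hi) {
        stop("could not place singleton background peaks; enlarge chromosomes",
             call. = FALSE)
      }
      bg_peaks[[length(bg_peaks) + 1]] <- data.frame(
        chrom = ch, start = st, end = st + widths[i] - 1L,
        value = stats::rlnorm(1, config$signal_low["meanlog"],
                              config$signal_low["sdlog"]),
        kind = "background", host = NA_character_, stringsAsFactors = FALSE)
      prev_end <- st + widths[i] - 1L
    }
  }
  peak_df <- do.call(rbind, c(unname(peaks), bg_peaks))
  rownames(peak_df) <- NULL

  # --- motif placements ----------------------------------------------------
  placements <- list()
  for (ci in seq_len(nrow(clusters))) {
    h <- clusters$host[ci]
    content <- planted_content(h, roles, config)
    taken <- IRanges::IRanges()
    for (src in names(content)) {
      for (k in seq_len(content[[src]])) {
        placed <- FALSE
        for (try in 1:400) {
          st <- as.integer(round(stats::runif(
            1, clusters$start[ci], clusters$end[ci] - w + 1L)))
          cand <- IRanges::IRanges(st - w, st + 2L * w - 1L) # pad: gap >= w
          if (length(IRanges::findOverlaps(cand, taken)) == 0) {
            taken <- c(taken, IRanges::IRanges(st, st + w - 1L))
            placements[[length(placements) + 1]] <- data.frame(
              motif_tf = src, host = h, chrom = clusters$chrom[ci],
              start = st, end = st + w - 1L,
              strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place motif instances; enlarge the clusters",
               call. = FALSE)
        }
      }
    }
  }
  placements <- do.call(rbind, placements)
  embed_instance <- function(p, pure = FALSE) {
    inst <- sample_pwm_instance(pwms[[p$motif_tf]], pure = pure)
    if (p$strand == "-") inst <- revcomp_codes(inst)
    genome_codes[[p$chrom]][p$start:p$end] <<- inst
  }
  for (i in seq_len(nrow(placements))) embed_instance(placements[i, ])

  # --- scrub-and-verify loop ----------------------------------------------
  pad <- as.integer(config$scan$extension + 200)
  models <- lapply(pwms, scan_model, params = config$scan)
  threshold <- config$scan$pvalue_threshold
  converged <- FALSE
  for (iter in 1:40) {
    hits <- scan_clusters(genome_codes, clusters, models, threshold, pad)
    dirty <- 0
    # spurious hits: everything except an exact-coordinate, same-strand
    # match of a planted placement
    for (i in seq_len(nrow(hits))) {
      ov <- placements$motif_tf == hits$motif_tf[i] &
        placements$chrom == hits$chrom[i] &
        placements$start == hits$start[i] &
        placements$strand == hits$strand[i]
      if (any(ov)) next
      dirty <- dirty + 1
      pos <- hits$start[i]:hits$end[i]
      covered <- rep(FALSE, length(pos))
      pl <- placements[placements$chrom == hits$chrom[i] &
                         placements$start <= hits$end[i] &
                         placements$end >= hits$start[i], , drop = FALSE]
      for (j in seq_len(nrow(pl))) {
        covered <- covered | (pos >= pl$start[j] & pos <= pl$end[j])
      }
      free <- pos[!covered]
      if (length(free)) {
        genome_codes[[hits$chrom[i]]][free] <-
          sample.int(4L, length(free), replace = TRUE, prob = base_prob)
      } else {
        for (j in seq_len(nrow(pl))) embed_instance(pl[j, ], pure = TRUE)
      }
    }
    # unrecovered placements: re-draw (pure consensus from the 2nd pass on)
    for (i in seq_len(nrow(placements))) {
      p <- placements[i, ]
      found <- any(hits$motif_tf == p$motif_tf & hits$host == p$host &
                     hits$start == p$start & hits$strand == p$strand)
      if (!found) {
        dirty <- dirty + 1
        embed_instance(p, pure = iter >= 2)
      }
    }
    if (dirty == 0) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("synthetic generator failed to converge to a clean epigenome",
         call. = FALSE)
  }

  # --- exactness check: hits inside each extended cluster == planted -------
  ext <- as.integer(config$scan$extension)
  hits <- scan_clusters(genome_codes, clusters, models, threshold, pad)
  cl_idx <- match(hits$host, clusters$host)
  inside <- hits$start >= clusters$start[cl_idx] - ext &
    hits$end <= clusters$end[cl_idx] + ext
  observed <- table(factor(hits$motif_tf[inside], levels = symbols),
                    factor(hits$host[inside], levels = clustered))
  expected <- matrix(0L, nrow = length(symbols), ncol = length(clustered),
                     dimnames = list(symbols, clustered))
  for (i in seq_len(nrow(placements))) {
    expected[placements$motif_tf[i], placements$host[i]] <-
      expected[placements$motif_tf[i], placements$host[i]] + 1L
  }
  if (!all(observed == expected)) {
    bad <- which(observed != expected, arr.ind = TRUE)
    stop(sprintf(
      "planted motif counts failed verification (%s)",
      paste(sprintf("%s in %s: %d planted, %d observed",
                    rownames(expected)[bad[, 1]],
                    colnames(expected)[bad[, 2]],
                    expected[bad], observed[bad]),
            collapse = "; ")), call. = FALSE)
  }

  # --- write files ---------------------------------------------------------
  genome <- Biostrings::DNAStringSet(vapply(genome_codes, decode_dna,
                                            character(1)))
  names(genome) <- chroms
  peak_ord <- order(peak_df$chrom, peak_df$start)
  peak_df <- peak_df[peak_ord, , drop = FALSE]
  peak_gr <- GenomicRanges::GRanges(
    seqnames = peak_df$chrom,
    ranges = IRanges::IRanges(peak_df$start, peak_df$end),
    strand = "*",
    name = sprintf("peak_%04d", seq_len(nrow(peak_df))),
    score = pmin(1000, round(peak_df$value * 10)),
    signalValue = peak_df$value,
    pValue = rep(-1, nrow(peak_df)), qValue = rep(-1, nrow(peak_df)),
    peak = rep(-1L, nrow(peak_df)))
  track <- GenomicRanges::GRanges(
    seqnames = peak_df$chrom,
    ranges = IRanges::IRanges(peak_df$start, peak_df$end),
    score = peak_df$value)

  files <- list(
    genome = file.path(out_dir, "genome.fa"),
    genes = file.path(out_dir, "genes.gtf"),
    peaks = file.path(out_dir, "peaks.narrowPeak"),
    signal = file.path(out_dir, "signal.bedGraph"),
    motifs = file.path(out_dir, "motifs.meme"),
    tf_list = file.path(out_dir, "tf_list.txt"),
    truth = file.path(out_dir, "truth.json"))
  write_genome(genome, files$genome)
  write_gtf_genes(genes, files$genes)
  write_narrowpeak(peak_gr, files$peaks)
  write_bedgraph(track, files$signal)
  write_meme_motifs(pwms, files$motifs)
  writeLines(symbols, files$tf_list)

  cluster_signal <- vapply(seq_len(nrow(clusters)), function(ci) {
    sel <- peak_df$kind == "cluster" & !is.na(peak_df$host) &
      peak_df$host == clusters$host[ci]
    sum(peak_df$value[sel] * (peak_df$end[sel] - peak_df$start[sel] + 1L))
  }, numeric(1))

  truth <- list(
    seed = config$seed,
    core_tfs = core,
    roles = list(pair = pair, trio = trio, singleton = singleton,
                 missing_edge = as.list(missing_edge)),
    # coordinates in truth.json are 0-based half-open (BED convention)
    clusters = data.frame(host = clusters$host, chrom = clusters$chrom,
                          start = clusters$start - 1L, end = clusters$end,
                          total_signal = cluster_signal,
                          is_core = clusters$host %in% core,
                          stringsAsFactors = FALSE),
    placements = data.frame(motif_tf = placements$motif_tf,
                            host = placements$host,
                            chrom = placements$chrom,
                            start = placements$start - 1L,
                            end = placements$end,
                            strand = placements$strand,
                            stringsAsFactors = FALSE),
    expected_counts = data.frame(
      source_tf = rep(rownames(expected), ncol(expected)),
      target_tf = rep(colnames(expected), each = nrow(expected)),
      count = as.integer(expected), stringsAsFactors = FALSE),
    self_motif_copies = config$self_motif_copies,
    k_core = config$k_core)
  writeLines(jsonlite::toJSON(truth, pretty = TRUE, digits = 10,
                              dataframe = "columns"), files$truth)
  invisible(list(dir = out_dir, files = files, truth = truth,
                 config = config))
}

#' Read a synthetic truth file
#' @param path Path to `truth.json`.
#' @return The truth list (data.frame components restored).
#' @export
read_truth <- function(path) {
  tr <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tr$clusters <- as.data.frame(tr$clusters)
  tr$placements <- as.data.frame(tr$placements)
  tr$expected_counts <- as.data.frame(tr$expected_counts)
  tr
}
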