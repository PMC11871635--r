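# PWM scanning: log-odds scoring, exact DP p-values, stranded hit calling
# and per-pair hit counting.

test_that("region extension clips at chromosome bounds", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
  ext <- extend_regions(gr, 500, c(chr1 = 100000))
  expect_equal(GenomicRanges::start(ext) - 1, 500)   # BED [500, 2500)
  expect_equal(GenomicRanges::end(ext), 2500)
  expect_equal(extend_regions(gr, 0), gr)
  near0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 400))
  expect_equal(GenomicRanges::start(extend_regions(near0, 500)), 1L)
  nearL <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99900, 99950))
  expect_equal(GenomicRanges::end(extend_regions(nearL, 500,
                                                 c(chr1 = 100000))),
               100000L)
})

test_that("log-odds matrix has the closed-form values", {
  # consensus ACGT with probability 1, no pseudocount, uniform background:
  # each consensus cell is log2(4), so the consensus window scores 8 bits
  probs <- diag(4)[, 1:4]
  p <- pwm_record("cons", "T", probs)
  m0 <- log_odds_matrix(p, rep(0.25, 4), pseudocount = 0)
  expect_equal(sum(m0[cbind(1:4, 1:4)]), 4 * log2(4))
  # uniform rows score 0 everywhere
  u <- pwm_record("u", "T", matrix(0.25, 4, 4))
  expect_equal(log_odds_matrix(u, rep(0.25, 4), 0.1),
               matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_error(log_odds_matrix(p, c(0, 0.5, 0.25, 0.25), 0.1), "positive")
})

test_that("log-odds matrix matches per-cell arithmetic on random PWMs", {
  set.seed(14)
  for (rep in 1:10) {
    pwm <- random_pwm(sample(4:12, 1))
    bg <- stats::runif(4, 0.1, 1); bg <- bg / sum(bg)
    pc <- stats::runif(1, 0, 1)
    m <- log_odds_matrix(pwm, bg, pc)
    want <- matrix(0, pwm_width(pwm), 4)
    for (j in seq_len(pwm_width(pwm))) for (b in 1:4) {
      want[j, b] <- log2(((pwm$probs[j, b] + pc * bg[b]) / (1 + pc)) / bg[b])
    }
    expect_equal(unname(m), want, tolerance = 1e-12)
  }
})

test_that("DP tail probabilities equal exhaustive enumeration for w <= 6", {
  set.seed(60)
  for (rep in 1:8) {
    w <- sample(3:6, 1)
    pwm <- random_pwm(w)
    bg <- rep(0.25, 4)
    lo <- log_odds_matrix(pwm, bg, 0.1)
    dist <- score_distribution(lo, bg, bins = 1000)
    words <- oracle_word_scores(lo, dist, bg)
    # exact on the shared integer scale
    for (k in sort(unique(words$ints))) {
      expect_equal(crcscan:::pvalue_from_int(dist, k),
                   sum(words$prob[words$ints >= k]), tolerance = 1e-12)
    }
    # real-score queries are right up to the discretisation band
    for (t in stats::quantile(words$real, c(0.1, 0.5, 0.9, 0.99))) {
      band <- w / (2 * dist$scale)
      p <- tail_probability(dist, t)
      expect_gte(p, sum(words$prob[words$real >= t + band]) - 1e-12)
      expect_lte(p, sum(words$prob[words$real >= t - band]) + 1e-12)
    }
    # extreme thresholds
    expect_equal(tail_probability(dist, min(words$real) - 1), 1)
    expect_equal(tail_probability(dist, max(words$real) + 1), 0)
    # total mass 1
    expect_equal(crcscan:::pvalue_from_int(dist, 0), 1, tolerance = 1e-9)
    # monotone non-increasing tail
    tl <- dist$tail
    expect_true(all(diff(tl) <= 1e-12))
  }
})

test_that("scanning finds a planted consensus and matches a naive rescorer", {
  set.seed(71)
  # p <= 1e-3 so that even a width-5 consensus (p = 0.25^5) is callable
  params <- crc_params(pvalue_threshold = 1e-3)
  for (rep in 1:5) {
    w <- sample(5:6, 1)
    pwm <- random_pwm(w, concentration = 0.2) # informative columns
    cons <- pwm_consensus(pwm)
    L <- 300
    seqs <- random_sequence(L)
    off <- sample(50:(L - w - 50), 1)
    substr(seqs, off, off + w - 1) <- cons
    hits <- scan_sequence(seqs, pwm, params)

    # naive oracle: per-window integer rescoring + exhaustive integer tails
    bg <- crcscan:::symmetrize_background(params$background)
    lo <- log_odds_matrix(pwm, bg, params$pseudocount)
    dist <- score_distribution(lo, bg, params$score_bins)
    words <- oracle_word_scores(lo, dist, bg)
    tail_int <- function(k) sum(words$prob[words$ints >= k])
    codes <- crcscan:::encode_dna(seqs)
    naive <- list()
    for (i in 1:(L - w + 1)) {
      for (strand in c("+", "-")) {
        win <- codes[i:(i + w - 1)]
        if (strand == "-") win <- crcscan:::revcomp_codes(win)
        ki <- sum(dist$ints[cbind(seq_len(w), win)])
        pv <- tail_int(ki)
        if (pv <= params$pvalue_threshold) {
          naive[[length(naive) + 1]] <- data.frame(
            start = i, strand = strand,
            score = sum(lo[cbind(seq_len(w), win)]), pvalue = pv)
        }
      }
    }
    naive <- do.call(rbind, naive)
    naive <- naive[order(naive$start, naive$strand), , drop = FALSE]
    expect_equal(hits$start, naive$start)
    expect_equal(hits$strand, naive$strand)
    expect_equal(hits$score, naive$score, tolerance = 1e-12)
    expect_equal(hits$pvalue, naive$pvalue, tolerance = 1e-12)
    # the planted consensus is among the + strand hits
    if (0.25^w <= params$pvalue_threshold) {
      expect_true(off %in% hits$start[hits$strand == "+"])
    }
  }
})

test_that("hits are symmetric under reverse-complementing the sequence", {
  set.seed(81)
  params <- crc_params()
  pwm <- random_pwm(6, concentration = 0.3)
  seqs <- random_sequence(400)
  off <- 100
  substr(seqs, off, off + 5) <- pwm_consensus(pwm)
  fwd <- scan_sequence(seqs, pwm, params)
  rev <- scan_sequence(revcomp_string(seqs), pwm, params)
  L <- nchar(seqs)
  w <- pwm_width(pwm)
  mirrored <- data.frame(start = L - w + 2 - rev$start,
                         strand = as.character(ifelse(rev$strand == "+", "-", "+")),
                         score = rev$score, pvalue = rev$pvalue)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(fwd$start, mirrored$start)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score, tolerance = 1e-12)
})

test_that("threshold 1 reports every window and N bases contribute zero", {
  params <- crc_params(pvalue_threshold = 1 - 1e-12)
  pwm <- random_pwm(5)
  seqs <- "ACGTACGTACGTACGTACGT"
  hits <- scan_sequence(seqs, pwm, params)
  expect_equal(nrow(hits), 2 * (nchar(seqs) - 5 + 1))
  # a window of Ns scores exactly 0 bits
  hn <- scan_sequence("NNNNN", pwm, params)
  expect_equal(hn$score, c(0, 0))
  # shorter than the motif: empty result
  expect_equal(nrow(scan_sequence("ACG", pwm, params)), 0)
})

test_that("hit counting aggregates per ordered TF pair with zero fill", {
  hits <- data.frame(
    motif_id = c("a_m", "a_m", "a_m", "b_m"),
    tf = c("A", "A", "A", "B"),
    region_id = c("r1", "r1", "r2", "r1"),
    start = 1:4, strand = "+", score = 1, pvalue = 1e-5)
  asg <- data.frame(se_id = c("r1", "r2", "r2"),
                    symbol = c("A", "A", "B"),
                    distance = 0, is_primary = TRUE)
  counts <- count_hits(hits, asg, source_tfs = c("A", "B"),
                       target_tfs = c("A", "B"))
  get <- function(s, t) counts$count[counts$source_tf == s &
                                       counts$target_tf == t]
  expect_equal(get("A", "A"), 3L)  # r1 (2 hits) + r2 (1 hit)
  expect_equal(get("A", "B"), 1L)  # r2 assigned to B too
  expect_equal(get("B", "A"), 1L)
  expect_equal(get("B", "B"), 0L)  # zero-filled pair
  # no assignments: all zero
  none <- count_hits(hits, asg[0, ], source_tfs = c("A", "B"),
                     target_tfs = c("A", "B"))
  expect_true(all(none$count == 0))
})

test_that("planted placements are recovered when scanning the synthetic SEs", {
  sim <- fixture_sim()
  truth <- sim$truth
  genome <- read_genome(sim$files$genome)
  pwms <- read_meme_motifs(sim$files$motifs)
  params <- crc_params()
  cl <- truth$clusters
  core <- truth$core_tfs
  pl <- truth$placements
  for (h in core[1:2]) {
    row <- cl[cl$host == h, ]
    reg <- GenomicRanges::GRanges(row$chrom,
                                  IRanges::IRanges(row$start + 1, row$end),
                                  region_id = h)
    ext <- extend_regions(reg, params$extension,
                          stats::setNames(Biostrings::width(genome),
                                          names(genome)))
    hits <- scan_regions(ext, genome, pwms, params)
    for (src in core) {
      n_hit <- sum(hits$tf == src)
      n_planted <- sum(pl$host == h & pl$motif_tf == src)
      expect_gte(n_planted, truth$self_motif_copies)
      expect_equal(n_hit, n_planted)
    }
  }
})
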