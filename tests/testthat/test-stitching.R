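# Promoter exclusion, gap-based stitching and signal quantification.

bed_peaks <- function(chrom, start0, end0, signal = 1) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                         strand = "*", name = ".", score = 0,
                         signalValue = signal, pValue = -1, qValue = -1,
                         peak = -1L)
}

test_that("promoter exclusion removes TSS-proximal midpoints, window 0 is identity", {
  genes <- crcscan:::gene_granges("chr1", 10000, 20000, "+", "G", "G")
  # midpoint at TSS+1000 (BED): peak [10800,11200) has midpoint 11000 = tss0+1001?
  p_near <- bed_peaks("chr1", 10800, 11200)   # midpoint 10999+1: within 2500
  p_far <- bed_peaks("chr1", 40000, 40500)
  peaks <- c(p_near, p_far)
  kept <- exclude_promoter_peaks(peaks, genes, 2500)
  expect_equal(length(kept), 1L)
  expect_equal(GenomicRanges::start(kept), 40001L)
  expect_identical(exclude_promoter_peaks(peaks, genes, 0), peaks)
  # boundary: midpoint exactly window away is removed (inclusive)
  tss0 <- genes$tss - 1
  pb <- bed_peaks("chr1", tss0 + 2500 - 50, tss0 + 2500 + 50) # midpoint tss0+2500
  expect_length(exclude_promoter_peaks(pb, genes, 2500), 0)
})

test_that("promoter exclusion matches the all-pairs distance oracle", {
  set.seed(42)
  for (rep in 1:5) {
    peaks <- random_peaks(500, max_pos = 3e5)
    genes <- crcscan:::gene_granges(
      sample(c("chr1", "chr2"), 30, TRUE),
      start <- sample.int(250000, 30), start + 5000,
      sample(c("+", "-"), 30, TRUE), sprintf("G%d", 1:30),
      sprintf("G%d", 1:30))
    w <- sample(c(0, 500, 2500, 10000), 1)
    got <- exclude_promoter_peaks(peaks, genes, w)
    want <- if (w == 0) peaks else oracle_promoter_filter(peaks, genes, w)
    expect_equal(regions_to_bed(got), regions_to_bed(want))
  }
})

test_that("stitching joins peaks iff chained gaps stay within distance", {
  p <- c(bed_peaks("chr1", 0, 100), bed_peaks("chr1", 200, 300))
  one <- stitch(p, 150)
  expect_equal(length(one), 1L)
  expect_equal(regions_to_bed(one), data.frame(chrom = "chr1", s = 0, e = 300))
  expect_equal(one$n_constituents, 2L)
  two <- stitch(p, 50)
  expect_equal(length(two), 2L)
  # gap is exactly 100: boundary inclusive
  expect_equal(length(stitch(p, 100)), 1L)
  expect_equal(length(stitch(p, 99)), 2L)
})

test_that("stitching equals the O(n^2) transitive-merge oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(20:300, 1)
    peaks <- random_peaks(n, max_pos = sample(c(2e4, 1e5, 5e5), 1))
    d <- sample(c(0, 100, 1000, 12500), 1)
    got <- stitch(peaks, d)
    expect_equal(regions_to_bed(got), oracle_stitch(peaks, d))
    expect_equal(sum(got$n_constituents), n)
  }
})

test_that("stitching is idempotent and monotone in distance", {
  set.seed(5)
  peaks <- random_peaks(400, max_pos = 4e5)
  r1 <- stitch(peaks, 2000)
  # restitching the region footprints changes nothing
  fake <- bed_peaks(as.character(GenomicRanges::seqnames(r1)),
                    GenomicRanges::start(r1) - 1L, GenomicRanges::end(r1))
  expect_equal(regions_to_bed(stitch(fake, 2000)), regions_to_bed(r1))
  # wider stitching never increases the region count
  ds <- c(0, 50, 500, 5000, 50000)
  counts <- vapply(ds, function(d) length(stitch(peaks, d)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("quantification integrates value over constituent footprints", {
  p <- bed_peaks("chr1", 0, 100)
  r <- stitch(p, 1000)
  tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), score = 2)
  expect_equal(quantify(r, tr)$signal, 200)
  # control equal to signal floors at zero
  expect_equal(quantify(r, tr, control = tr)$signal, 0)
  # fallback sums constituent signalValues
  expect_equal(quantify(r)$signal, 1)
})

test_that("quantification matches a per-base summation oracle", {
  set.seed(13)
  peaks <- random_peaks(25, chroms = "chr1", max_pos = 5000,
                        width_range = c(20, 80))
  regions <- stitch(peaks, 300)
  starts <- cumsum(sample(30:150, 30, TRUE))
  track <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts, width = sample(10:25, 30, TRUE)),
    score = stats::runif(30, 0, 5))
  got <- quantify(regions, track)$signal
  expect_equal(got, oracle_region_signal(regions, track), tolerance = 1e-9)
})

test_that("signal is conserved across stitching for disjoint peaks", {
  set.seed(77)
  starts <- cumsum(sample(500:2000, 60, TRUE))
  peaks <- bed_peaks("chr1", starts, starts + sample(50:200, 60, TRUE),
                     signal = stats::runif(60, 0, 10))
  r <- quantify(stitch(peaks, 1200))
  expect_equal(sum(r$signal), sum(peaks$signalValue))
  # with a track: region sums equal per-peak track sums
  track <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts + 1L, starts + 40L),
    score = stats::runif(60, 0, 3))
  r2 <- quantify(stitch(peaks, 1200), track)
  expect_equal(sum(r2$signal), signal_mass(track))
})
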