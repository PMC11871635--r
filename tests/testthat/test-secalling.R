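# Hockey-stick cutoff, super-enhancer flagging and gene assignment.

test_that("all-equal signals give a degenerate cutoff and zero supers", {
  res <- hockey_stick_cutoff(c(1, 1, 1, 1))
  expect_equal(res$cutoff_index, 4L)
  expect_equal(res$n_super, 0)
})

test_that("cutoff equals exhaustive tangent search on structured curves", {
  s <- (1:100)^2
  got <- hockey_stick_cutoff(s)
  want <- oracle_hockey(s)
  expect_equal(got$cutoff_index, want$cutoff_index)
  expect_equal(got$cutoff, want$cutoff)

  # two-segment piecewise-linear curve with slopes m/2 and 2m around the
  # break: the tangent lands at the breakpoint (within its flanking pair)
  n <- 200
  brk <- 120
  s2 <- c(seq(0, 50, length.out = brk),
          50 + seq_len(n - brk) * (2 * 50 / brk))
  got2 <- hockey_stick_cutoff(s2)
  want2 <- oracle_hockey(s2)
  expect_equal(got2$cutoff_index, want2$cutoff_index)
  expect_true(abs(got2$cutoff_index - brk) <= 1)
})

test_that("cutoff matches the rank-statistic oracle on random curves", {
  set.seed(1234)
  for (rep in 1:30) {
    n <- sample(2:800, 1)
    s <- switch(sample(3, 1),
                stats::rlnorm(n, 5, 1),
                sort(stats::runif(n, 0, 100))^sample(1:3, 1),
                c(stats::runif(n - 1, 0, 10),
                  stats::runif(1, 50, 100)))
    got <- hockey_stick_cutoff(s)
    want <- oracle_hockey(s)
    expect_equal(got$cutoff_index, want$cutoff_index)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("cutoff is scale-equivariant and stable to adding a low region", {
  set.seed(55)
  for (rep in 1:10) {
    s <- stats::rlnorm(sample(10:200, 1), 4, 1.5)
    base <- hockey_stick_cutoff(s)
    scaled <- hockey_stick_cutoff(s * 7.3)
    expect_equal(scaled$cutoff, base$cutoff * 7.3, tolerance = 1e-12)
    expect_equal(scaled$cutoff_index, base$cutoff_index)
    # membership unchanged
    expect_equal(sum(s > base$cutoff), scaled$n_super)
    # adding a region below the minimum never evicts an existing super
    super_before <- sort(s[s > base$cutoff])
    s2 <- c(s, min(s) * 0.5)
    res2 <- hockey_stick_cutoff(s2)
    expect_true(all(super_before %in% s2[s2 > res2$cutoff]))
  }
})

test_that("call_superenhancers ranks, flags and is order-invariant", {
  tab <- small_enhancer_table()
  r <- tab$regions
  expect_true(!is.unsorted(r$signal))
  expect_equal(r$rank, seq_along(r))
  expect_equal(r$is_super, r$signal > tab$cutoff)

  # shuffling input order leaves the super set unchanged
  set.seed(7)
  regions <- quantify(stitch(random_peaks(40, max_pos = 2e5), 5000))
  shuffled <- call_superenhancers(regions[sample(length(regions))])
  expect_equal(sort(shuffled$regions$region_id[shuffled$regions$is_super]),
               sort(r$region_id[r$is_super]))

  # single region is typical; empty input errors
  one <- quantify(stitch(random_peaks(1), 100))
  t1 <- call_superenhancers(one)
  expect_false(any(t1$regions$is_super))
  expect_error(call_superenhancers(one[0]), "no regions")
  expect_error(call_superenhancers(stitch(random_peaks(3), 10)),
               "not quantified")
})

test_that("gene assignment respects the window boundary exactly", {
  set.seed(8)
  peaks <- random_peaks(30, chroms = "chr1", max_pos = 1e5)
  regions <- quantify(stitch(peaks, 5000))
  regions$signal[which.max(regions$signal)] <- max(regions$signal) * 50
  tab <- call_superenhancers(regions)
  se <- tab$regions[tab$regions$is_super][1]
  s0 <- GenomicRanges::start(se) - 1
  e0 <- GenomicRanges::end(se)
  w <- 5000
  mk_gene <- function(tss0, sym) {
    crcscan:::gene_granges("chr1", tss0 + 1, tss0 + 2000, "+", sym, sym)
  }
  genes <- c(mk_gene(s0 + 5, "INSIDE"),
             mk_gene(e0 - 1 + w, "EDGE"),
             mk_gene(e0 - 1 + w + 1, "BEYOND"))
  asg <- assign_genes(tab, genes, window = w)
  expect_true("INSIDE" %in% asg$symbol)
  expect_equal(asg$distance[asg$symbol == "INSIDE"], 0)
  expect_true("EDGE" %in% asg$symbol)
  expect_equal(asg$distance[asg$symbol == "EDGE"], w)
  expect_false("BEYOND" %in% asg$symbol)
  # restriction to a TF list filters symbols
  asg2 <- assign_genes(tab, genes, window = w, restrict_to = c("EDGE"))
  expect_equal(unique(asg2$symbol), "EDGE")
})

test_that("gene assignment equals the all-pairs oracle with primary flags", {
  set.seed(31)
  for (rep in 1:5) {
    peaks <- random_peaks(60, max_pos = 3e5)
    tab <- call_superenhancers(quantify(stitch(peaks, 4000)))
    gstart <- sample.int(280000, 40)
    genes <- crcscan:::gene_granges(
      sample(c("chr1", "chr2"), 40, TRUE), gstart, gstart + 3000,
      sample(c("+", "-"), 40, TRUE), sprintf("G%02d", 1:40),
      sprintf("G%02d", 1:40))
    w <- sample(c(0, 1000, 20000), 1)
    got <- assign_genes(tab, genes, window = w)
    want <- oracle_assign(tab, genes, w)
    expect_equal(got[, c("se_id", "symbol", "distance")],
                 want, ignore_attr = TRUE)
    # the primary gene minimises distance within its SE
    if (nrow(got)) {
      for (id in unique(got$se_id)) {
        sub <- got[got$se_id == id, ]
        expect_equal(sub$distance[sub$is_primary], min(sub$distance))
      }
    }
  }
})
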