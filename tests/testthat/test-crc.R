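# Regulatory graph construction, the strict autoregulation rule, circuitry
# enumeration and occurrence-frequency scoring.

counts_df <- function(mat) {
  data.frame(source_tf = rep(rownames(mat), ncol(mat)),
             target_tf = rep(colnames(mat), each = nrow(mat)),
             count = as.integer(mat))
}

square <- function(tfs, fill = 0) {
  matrix(fill, length(tfs), length(tfs), dimnames = list(tfs, tfs))
}

test_that("graph edges require edge_min and missing pairs count zero", {
  g0 <- build_graph(data.frame(source_tf = character(0),
                               target_tf = character(0),
                               count = integer(0)),
                    tfs = c("A", "B"))
  expect_true(all(g0$counts == 0))
  m <- square(c("A", "B"))
  m["A", "B"] <- 1
  g <- build_graph(counts_df(m), tfs = c("A", "B"), edge_min = 2L)
  expect_true(g$counts["A", "B"] < g$edge_min) # count below edge_min: no edge
  expect_equal(nrow(enumerate_circuitries(g, self_threshold = -1)), 0)
})

test_that("autoregulation needs strictly more than two self hits", {
  m <- square(c("A", "B", "C"))
  diag(m) <- c(3, 2, 0)
  g <- build_graph(counts_df(m), tfs = rownames(m))
  expect_equal(autoregulated_tfs(g), "A")   # 3 > 2 in; 2 and 0 out
  expect_equal(autoregulated_tfs(g, self_threshold = 1), c("A", "B"))
})

test_that("a complete autoregulated triangle yields its downward closure", {
  m <- square(c("A", "B", "C"), fill = 1)
  diag(m) <- 3
  g <- build_graph(counts_df(m), tfs = rownames(m))
  circ <- enumerate_circuitries(g)
  expect_setequal(circ$key, c("A,B", "A,C", "B,C", "A,B,C"))
  expect_equal(circ$key[circ$is_maximal], "A,B,C")
  # dropping one direction removes every circuitry containing that pair
  m2 <- m; m2["A", "B"] <- 0
  g2 <- build_graph(counts_df(m2), tfs = rownames(m2))
  circ2 <- enumerate_circuitries(g2)
  expect_setequal(circ2$key, c("A,C", "B,C"))
  # no autoregulated TFs: empty result
  m3 <- m; diag(m3) <- 2
  expect_equal(nrow(enumerate_circuitries(
    build_graph(counts_df(m3), tfs = rownames(m3)))), 0)
})

test_that("enumeration equals brute-force power-set filtering", {
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    tfs <- sprintf("T%02d", seq_len(n))
    m <- square(tfs)
    m[] <- sample(0:2, n * n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    diag(m) <- sample(0:5, n, replace = TRUE)
    g <- build_graph(counts_df(m), tfs = tfs)
    circ <- enumerate_circuitries(g)
    expect_equal(sort(circ$key), oracle_circuitries(m, 1, 2))
    # downward closure: every size >= 2 subset of a circuitry is present
    for (i in seq_len(nrow(circ))) {
      mem <- circ$members[[i]]
      if (length(mem) > 2) {
        for (drop in seq_along(mem)) {
          expect_true(paste(mem[-drop], collapse = ",") %in% circ$key)
        }
      }
    }
  }
})

test_that("node limit guards unbounded enumeration", {
  tfs <- sprintf("T%02d", 1:30)
  m <- square(tfs, fill = 1)
  diag(m) <- 3
  g <- build_graph(counts_df(m), tfs = tfs)
  expect_error(enumerate_circuitries(g), "max_size")
  capped <- enumerate_circuitries(g, max_size = 2)
  expect_equal(nrow(capped), choose(30, 2))
})

test_that("the toy universe scores by occurrence frequency", {
  # A,B,C fully interconnected; D wired only to A; all autoregulated.
  tfs <- c("A", "B", "C", "D")
  m <- square(tfs)
  diag(m) <- 3
  for (p in list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "D"))) {
    m[p[1], p[2]] <- 1
    m[p[2], p[1]] <- 1
  }
  g <- build_graph(counts_df(m), tfs = tfs)
  circ <- enumerate_circuitries(g)
  expect_setequal(circ$key, c("A,B", "A,C", "B,C", "A,B,C", "A,D"))
  scored <- score_circuitries(circ)
  occ <- attr(scored, "occurrence")
  expect_equal(occ[c("A", "B", "C", "D")], c(A = 4L, B = 3L, C = 3L, D = 1L))
  sc <- function(k) scored$score[scored$key == k]
  expect_equal(sc("A,B,C"), 10 / 3)
  expect_equal(sc("A,D"), 2.5)
  # under the occurrence formula the high-occ pairs outrank the triple...
  expect_equal(sc("A,B"), 3.5)
  expect_equal(scored$key[1], "A,B")
  # ...but among maximal candidate circuitries the triple ranks first
  expect_equal(top_circuitry(scored, maximal_only = TRUE), c("A", "B", "C"))
  # independent recount over the emitted universe reproduces every score
  for (i in seq_len(nrow(scored))) {
    mem <- scored$members[[i]]
    occ2 <- vapply(mem, function(t) {
      sum(vapply(scored$members, function(mm) t %in% mm, logical(1)))
    }, numeric(1))
    expect_equal(scored$score[i], sum(occ2) / length(mem))
  }
})

test_that("single pair scores 1 and symmetric cliques rank the full set first", {
  m <- square(c("A", "B"), fill = 1)
  diag(m) <- 3
  scored <- score_circuitries(enumerate_circuitries(
    build_graph(counts_df(m), tfs = c("A", "B"))))
  expect_equal(scored$score, 1)
  for (k in 3:6) {
    tfs <- LETTERS[seq_len(k)]
    mk <- square(tfs, fill = 1)
    diag(mk) <- 3
    scored <- score_circuitries(enumerate_circuitries(
      build_graph(counts_df(mk), tfs = tfs)))
    # every circuitry of a symmetric clique shares the same score
    expect_equal(length(unique(scored$score)), 1)
    # the full set attains the top score and ranks first by the size tie-break
    expect_equal(scored$members[[1]], tfs)
    expect_equal(scored$size[1], k)
  }
})

test_that("reports are deterministic and degrade to headers when empty", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m <- square(c("A", "B", "C"), fill = 2)
  diag(m) <- 4
  g <- build_graph(counts_df(m), tfs = rownames(m))
  scored <- score_circuitries(enumerate_circuitries(g))
  report_crc(g, scored, d1)
  report_crc(g, scored, d2)
  expect_identical(readLines(file.path(d1, "circuitries.tsv")),
                   readLines(file.path(d2, "circuitries.tsv")))
  expect_identical(readLines(file.path(d1, "edges.tsv")),
                   readLines(file.path(d2, "edges.tsv")))
  g0 <- build_graph(counts_df(square(c("A", "B"))), tfs = c("A", "B"))
  s0 <- score_circuitries(enumerate_circuitries(g0))
  report_crc(g0, s0, d1)
  expect_equal(length(readLines(file.path(d1, "circuitries.tsv"))), 1L)
})
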