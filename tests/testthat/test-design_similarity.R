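test_that("DS score matches hand-derived values and edge cases", {
  # a segment shared by every plasmid carries no authorship signal
  expect_equal(ds_score(100, 100), 0)
  expect_equal(ds_score(7, 7), 0)
  expect_equal(ds_score(2, 1000), log(500), tolerance = 1e-12)
  expect_equal(ds_score(c(2, 10, 100), 1000), log(500 + (100 + 10) / 3),
               tolerance = 1e-12)
  # input order invariance (sorted internally)
  expect_identical(ds_score(c(100, 2, 10), 1000), ds_score(c(2, 10, 100), 1000))
  expect_error(ds_score(integer(0), 10), "undefined")
  expect_error(ds_score(c(0, 2), 10), ">= 1")
  expect_error(ds_score(c(2, 20), 10), "p must be")
})

test_that("DS score is monotone: decreasing in x1, increasing in p", {
  base <- ds_score(c(5, 40, 200), 1000)
  expect_gt(ds_score(c(4, 40, 200), 1000), base)
  expect_lt(ds_score(c(6, 40, 200), 1000), base)
  expect_gt(ds_score(c(5, 40, 200), 1200), base)
  # adding a segment strictly rarer than all existing ones increases the score
  expect_gt(ds_score(c(3, 5, 40, 200), 1000), base)
})

test_that("calibration is deterministic, honors ties, and rejects single labs", {
  set.seed(30)
  # four identical plasmids from four labs: every cross-lab score is ln(1) = 0
  s <- rdna(800)
  corpus <- plasmid_corpus(sprintf("c%d", 1:4), rep(s, 4),
                           sprintf("lab%d", 1:4))
  idx <- build_segment_index(corpus)
  suppressMessages(
    cal <- calibrate_cutoff(corpus, idx, n_pairs = 100, seed = 5))
  expect_true(cal$exhaustive)
  expect_equal(cal$n_pairs, 6)
  expect_equal(unique(cal$scores), 0)
  expect_equal(cal$cutoff, 0)
  # strict exceedance: all-tied sample gives a zero false-positive rate
  expect_equal(sum(cal$scores > cal$cutoff), 0)
  one_lab <- plasmid_corpus(c("u", "v"), c(s, s), c("same", "same"))
  expect_error(calibrate_cutoff(one_lab, idx), "two labs")
})

test_that("nearest-rank percentile bounds the strictly-above count", {
  scores <- c(1.5, -Inf, 3.2, 0.7, 2.2, 2.2, 9, 4, 0, 1)
  cut <- plasmidDS:::nearest_rank_percentile(scores, 95)
  expect_equal(cut, sort(scores)[ceiling(0.95 * 10)])
  expect_lte(sum(scores > cut), floor(0.05 * 10))
  # sentinel -Inf always ranks below every cutoff
  expect_true(all(-Inf <= sort(scores)))
})

test_that("binarize applies strict exceedance symmetrically", {
  ids <- c("a", "b", "c")
  mat <- matrix(c(NA, 3, 1, 3, NA, 2, 1, 2, NA), 3, 3,
                dimnames = list(ids, ids))
  adj <- binarize(mat, 2)
  expect_identical(adj, t(adj))
  expect_false(any(diag(adj)))
  expect_true(adj["a", "b"])
  expect_false(adj["b", "c"])  # exactly at the cutoff: no edge
  expect_false(adj["a", "c"])
  # brute-force elementwise comparison oracle
  set.seed(31)
  m <- matrix(runif(25), 5, 5); m <- (m + t(m)) / 2; diag(m) <- NA
  dimnames(m) <- list(letters[1:5], letters[1:5])
  cut <- 0.5
  adj2 <- binarize(m, cut)
  for (i in 1:5) for (j in 1:5) {
    expected <- if (i == j) FALSE else m[i, j] > cut
    expect_identical(unname(adj2[i, j]), expected)
  }
})

test_that("pairwise DS is symmetric and flags segment-free pairs as -Inf", {
  set.seed(32)
  common <- rdna(300)
  seqs <- c(paste0(rdna(200), common, rdna(150)),
            paste0(rdna(180), common, rdna(170)),
            rdna(650))
  corpus <- plasmid_corpus(c("w1", "w2", "w3"), seqs,
                           c("lab1", "lab2", "lab3"))
  idx <- build_segment_index(corpus)
  mat <- pairwise_ds(c("w1", "w2", "w3"), corpus, idx)
  expect_identical(mat, t(mat))
  expect_true(all(is.na(diag(mat))))
  expect_equal(mat["w1", "w2"], log(3 / 2))   # one segment in 2 of p = 3
  expect_identical(mat["w1", "w3"], -Inf)
  expect_identical(mat["w2", "w3"], -Inf)
})
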