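test_that("identical circular plasmids share one full-length segment", {
  set.seed(20)
  s <- rdna(1500)
  seg <- shared_segments(s, s)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length, 1500)
  expect_equal(seg$identity, 1)
})

test_that("independent random sequences share nothing", {
  set.seed(21)
  a <- rdna(3000); b <- rdna(3000)
  # brute-force 28-mer intersection (both strands) confirms zero seeds
  kmers <- function(x) {
    n <- nchar(x)
    substring(x, 1:(n - 27), 28:n)
  }
  shared <- intersect(kmers(paste0(a, a)),
                      c(kmers(paste0(b, b)), kmers(revcomp(paste0(b, b)))))
  expect_length(shared, 0)
  expect_equal(nrow(shared_segments(a, b)), 0)
})

test_that("a planted block is recovered with exact coordinates, either strand", {
  set.seed(22)
  block <- rdna(100)
  a <- paste0(rdna(500), block, rdna(400))
  b <- paste0(rdna(300), block, rdna(600))
  seg <- shared_segments(a, b, circular_a = FALSE, circular_b = FALSE)
  expect_equal(nrow(seg), 1)
  # the planted block is covered; endpoints may pick up a few chance
  # matches from the flanks (extension stops at the running maximum)
  expect_lte(seg$a_start, 500); expect_gte(seg$a_end, 600)
  expect_lte(seg$length, 110)
  expect_equal(seg$a_start - seg$b_start, 200)  # same diagonal as planted
  expect_equal(seg$strand_b, "+")
  expect_equal(seg$identity, 1)
  expect_true(grepl(block, seg$seq, fixed = TRUE))
  b2 <- paste0(rdna(250), revcomp(block), rdna(650))
  seg2 <- shared_segments(a, b2, circular_a = FALSE, circular_b = FALSE)
  expect_equal(seg2$strand_b, "-")
  expect_lte(seg2$b_start, 250); expect_gte(seg2$b_end, 350)
  expect_true(grepl(block, seg2$seq, fixed = TRUE))
})

test_that("segment sets are symmetric in the pair order", {
  set.seed(23)
  shared1 <- rdna(150); shared2 <- rdna(90)
  a <- paste0(rdna(300), shared1, rdna(200), shared2, rdna(250))
  b <- paste0(rdna(100), shared2, rdna(350), shared1, rdna(150))
  sab <- shared_segments(a, b, circular_a = FALSE, circular_b = FALSE)
  sba <- shared_segments(b, a, circular_a = FALSE, circular_b = FALSE)
  expect_equal(sort(sab$seq), sort(sba$seq))
  expect_equal(nrow(sab), 2)
})

test_that("wrap-around segments are found once with modular coordinates", {
  set.seed(24)
  block <- rdna(120)
  b <- paste0(rdna(200), block, rdna(500))
  # block split across the linearization origin of a
  a <- paste0(substr(block, 61, 120), rdna(700), substr(block, 1, 60))
  seg <- shared_segments(a, b)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length, 120)
  expect_equal(seg$a_start, 760)
  expect_gt(seg$a_end, nchar(a))  # wraps
  # rotation of a circular plasmid leaves segment content unchanged
  a_rot <- plasmidDS:::rotate_sequence(a, 333)
  seg_rot <- shared_segments(a_rot, b)
  expect_equal(seg_rot$seq, seg$seq)
})

test_that("the postings index supports candidate and monotonicity queries", {
  set.seed(25)
  s <- rdna(500)
  corpus2 <- plasmid_corpus(c("x", "y"), c(s, s), c("l1", "l2"))
  idx <- build_segment_index(corpus2)
  # every 28-mer of the shared sequence posts both plasmids
  for (off in c(0, 100, 400)) {
    w <- substr(s, off + 1, off + 28)
    expect_equal(plasmidDS:::cpp_query_candidates(idx$ptr, w), c(1L, 2L))
  }
  expect_length(plasmidDS:::cpp_query_candidates(idx$ptr, rdna(28)), 0)
  expect_error(build_segment_index(corpus2, word_size = 3), "word")
  # adding a plasmid only grows postings
  corpus3 <- plasmid_corpus(c("x", "y", "z"), c(s, s, rdna(600)),
                            c("l1", "l2", "l3"))
  idx3 <- build_segment_index(corpus3)
  w <- substr(s, 51, 78)
  expect_true(all(plasmidDS:::cpp_query_candidates(idx$ptr, w) %in%
                    plasmidDS:::cpp_query_candidates(idx3$ptr, w)))
})

test_that("segment frequency counts distinct containing plasmids", {
  set.seed(26)
  segment <- rdna(150)
  # 5% divergent copy: below the 98% identity bar
  far <- segment
  for (pos in seq(5, 145, by = 20)) far <- substitute_at(far, pos)
  seqs <- c(vapply(1:7, function(i) paste0(rdna(400), segment, rdna(300)), ""),
            vapply(1:4, function(i) rdna(850), ""),
            paste0(rdna(400), far, rdna(300)))
  corpus <- plasmid_corpus(sprintf("p%02d", 1:12), seqs,
                           sprintf("lab%02d", 1:12))
  idx <- build_segment_index(corpus)
  expect_equal(segment_frequency(segment, idx), 7)
  # memoized
  expect_equal(segment_frequency(segment, idx), 7)
  # a segment coming from a pair comparison is contained in both members
  segs <- shared_segments(seqs[1], seqs[2])
  fv <- frequency_vector(segs, idx)
  expect_true(all(fv$x >= 2))
})

test_that("frequency vectors are sorted ascending", {
  expect_equal(frequency_vector(plasmidDS:::empty_segment_df(), NULL),
               list(x = integer(0), n = 0L))
  # sorting contract via ds_score input handling
  expect_equal(sort(c(5L, 2L, 900L)), c(2L, 5L, 900L))
  set.seed(27)
  block_a <- rdna(120); block_b <- rdna(90)
  common <- rdna(200)
  mk <- function(extra) paste0(rdna(150), common, rdna(100), extra, rdna(120))
  seqs <- c(mk(paste0(block_a, rdna(40), block_b)),
            mk(paste0(block_a, rdna(55), block_b)),
            mk(""), mk(""), mk(""))
  corpus <- plasmid_corpus(sprintf("q%d", 1:5), seqs, sprintf("lab%d", 1:5))
  idx <- build_segment_index(corpus)
  segs <- shared_segments(seqs[1], seqs[2])
  fv <- frequency_vector(segs, idx)
  expect_equal(fv$n, nrow(segs))
  expect_false(is.unsorted(fv$x))
  # the common block is in all 5, the private blocks in 2
  expect_true(5 %in% fv$x)
  expect_true(2 %in% fv$x)
})

test_that("segment frequency is invariant to rotating a corpus plasmid", {
  set.seed(28)
  segment <- rdna(140)
  seqs <- c(paste0(rdna(300), segment, rdna(200)),
            paste0(rdna(250), segment, rdna(350)),
            rdna(700))
  corpus1 <- plasmid_corpus(c("r1", "r2", "r3"), seqs, c("a", "b", "c"))
  seqs2 <- seqs
  seqs2[2] <- plasmidDS:::rotate_sequence(seqs2[2], 411)
  corpus2 <- plasmid_corpus(c("r1", "r2", "r3"), seqs2, c("a", "b", "c"))
  f1 <- segment_frequency(segment, build_segment_index(corpus1))
  f2 <- segment_frequency(segment, build_segment_index(corpus2))
  expect_equal(f1, 2)
  expect_equal(f2, 2)
})
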