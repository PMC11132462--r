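test_that("FASTA corpus round-trips with identical sequences, ids and labs", {
  set.seed(1)
  corpus <- plasmid_corpus(c("pA", "pB", "pC"),
                           c(rdna(300), rdna(250), rdna(400)),
                           c("Lab One", "lab one ", "Lab Two"))
  expect_equal(corpus$p, 3)
  # lab normalization: trimming + case folding collapses the first two labs
  expect_equal(unique(corpus$plasmids$lab_id), c("lab one", "lab two"))
  fa <- tempfile(fileext = ".fasta"); md <- tempfile(fileext = ".tsv")
  write_corpus(corpus, fa, md)
  back <- read_corpus(fa, md)
  expect_identical(back$sequences, corpus$sequences)
  expect_identical(back$plasmids$lab_id, corpus$plasmids$lab_id)
  expect_equal(back$p, 3)
})

test_that("corpus reader enforces metadata completeness and unique ids", {
  set.seed(2)
  fa <- tempfile(fileext = ".fasta"); md <- tempfile(fileext = ".tsv")
  writeLines(c(">pX", rdna(100), ">pY", rdna(100)), fa)
  writeLines(c("plasmid_id\tlab_id", "pY\tlab b"), md)
  expect_error(read_corpus(fa, md), "pX")
  expect_error(plasmid_corpus(c("a", "a"), c("ACGT", "ACGT"),
                              c("l1", "l2")), "duplicate")
  expect_error(plasmid_corpus("a", "ACGT", "  "), "lab_id")
  expect_error(plasmid_corpus("a", "", "l1"), "empty sequence")
})

test_that("GenBank records carry their own topology; FASTA uses the default", {
  gb <- system.file("extdata", "example.gb", package = "plasmidDS")
  md <- system.file("extdata", "example_gb_metadata.tsv", package = "plasmidDS")
  corpus <- read_corpus(gb, md)
  expect_equal(corpus$plasmids$circular, c(TRUE, FALSE))
  expect_equal(corpus$p, 2)
  expect_true(all(grepl("^[ACGT]+$", corpus$sequences)))
  fa <- system.file("extdata", "example_corpus.fasta", package = "plasmidDS")
  md2 <- system.file("extdata", "example_metadata.tsv", package = "plasmidDS")
  expect_true(all(read_corpus(fa, md2)$plasmids$circular))
  expect_false(any(read_corpus(fa, md2,
                               circular_default = FALSE)$plasmids$circular))
})

test_that("ambiguity codes are rejected by default and substituted on request", {
  expect_error(normalize_sequence("ACGRT"), "non-ACGT")
  expect_equal(normalize_sequence("ACGRT", on_ambiguous = "replace"), "ACGAT")
  expect_equal(normalize_sequence("acgt"), "ACGT")
})

test_that("part database reader validates categories and CDS lengths", {
  db <- read_part_db(
    system.file("extdata", "example_parts.fasta", package = "plasmidDS"),
    system.file("extdata", "example_parts.tsv", package = "plasmidDS"))
  expect_equal(nrow(db), 3)
  expect_true(all(db$aa_ok))
  fa <- tempfile(fileext = ".fasta"); md <- tempfile(fileext = ".tsv")
  writeLines(c(">pt1", "ACGTACGTACGT"), fa)
  writeLines(c("part_id\tname\tcategory\tis_cds", "pt1\tx\torign\tFALSE"), md)
  expect_error(read_part_db(fa, md), "origin of replication")
  # CDS whose length is not a multiple of 3: accepted with a warning,
  # amino-acid comparisons disabled
  expect_warning(
    db2 <- part_db("p1", category = "CDS", is_cds = TRUE,
                   sequence = paste(rep("ACGTA", 20), collapse = "")),
    "divisible by 3")
  expect_false(db2$aa_ok)
})

test_that("variant report CSV is deterministic, sorted and properly quoted", {
  path <- tempfile(fileext = ".csv")
  empty <- plasmidDS:::empty_report_df()
  write_variant_report(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
  reports <- data.frame(
    part_id = c("a,b", "z", "m"), category = "promoter",
    variant_key = c("k3", "k1", "k2"),
    n_observations = c(5L, 9L, 2L), n_labs = c(3L, 21L, 3L),
    n_clusters = c(2L, NA, 1L),
    classification = c("convergent", "widespread", "neither"),
    variant_sequence = "ACGT", stringsAsFactors = FALSE)
  out <- write_variant_report(reports, path)
  expect_equal(out$classification, c("widespread", "convergent", "neither"))
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$part_id[2], "a,b")  # comma survives quoting
  expect_equal(nrow(back), 3)
})
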