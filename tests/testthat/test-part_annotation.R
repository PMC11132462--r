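test_that("a plasmid equal to a canonical part annotates perfectly", {
  set.seed(50)
  part <- rdna(400)
  db <- part_db("pt1", category = "promoter", is_cds = FALSE,
                sequence = part)
  m <- annotate_plasmid(part, db, circular = FALSE)
  expect_equal(nrow(m), 1)
  expect_equal(m$coverage, 1)
  expect_equal(m$nt_identity, 1)
  expect_equal(m$strand, "+")
  expect_equal(m$matched_sequence, part)
})

test_that("wrap-around and reverse-strand embeddings are found", {
  set.seed(51)
  part <- rdna(1000)
  db <- part_db("big", category = "origin of replication", is_cds = FALSE,
                sequence = part)
  # 500 nt at the sequence end + 500 nt at the start (circular origin)
  plasmid <- paste0(substr(part, 501, 1000), rdna(900),
                    substr(part, 1, 500))
  m <- annotate_plasmid(plasmid, db, circular = TRUE)
  expect_equal(nrow(m), 1)
  expect_equal(m$coverage, 1)
  expect_equal(m$nt_identity, 1)
  expect_gt(m$end, nchar(plasmid))  # wrap-around coordinates
  # brute-force confirmation on the doubled sequence
  expect_equal(regexpr(part, paste0(plasmid, plasmid), fixed = TRUE)[1] - 1,
               m$start)
  # reverse strand
  m2 <- annotate_plasmid(paste0(rdna(300), revcomp(part), rdna(200)), db,
                         circular = FALSE)
  expect_equal(m2$strand, "-")
  expect_equal(m2$matched_sequence, part)
})

test_that("single substitutions give the hand-computed identity", {
  set.seed(52)
  part <- rdna(200)
  db <- part_db("p200", category = "promoter", is_cds = FALSE,
                sequence = part)
  plasmid <- paste0(rdna(150), substitute_at(part, 101), rdna(180))
  m <- annotate_plasmid(plasmid, db, circular = FALSE)
  expect_equal(m$coverage, 1)
  expect_equal(m$nt_identity, 199 / 200)
})

test_that("variant filters drop canonical, silent and terminally-deleted matches", {
  toy <- make_toy_corpus()
  matches <- annotate_corpus(toy$corpus, toy$db)
  variants <- filter_matches(matches, toy$db)
  keys <- paste0(variants$part_id, ":", variants$matched_sequence)
  # silent CDS change on p01: annotated but filtered
  expect_true(any(matches$plasmid_id == "p01" & matches$part_id == "cdsA"))
  expect_false("p01" %in% variants$plasmid_id)
  # 5'-truncated CDS on p02: covered >= 95% but terminally deleted
  p02 <- matches[matches$plasmid_id == "p02" & matches$part_id == "cdsA", ]
  expect_equal(nrow(p02), 1)
  expect_gte(p02$coverage, 0.95)
  expect_gt(p02$q_start, 0)
  expect_false("p02" %in% variants$plasmid_id)
  # sub-threshold coverage promoter on p03: not even annotated
  expect_false(any(matches$plasmid_id == "p03" & matches$part_id == "promB"))
  # fully canonical plasmid contributes no variants
  expect_false("p10" %in% variants$plasmid_id)
  expect_setequal(unique(keys), unlist(toy$expected))
})

test_that("variant records aggregate observations and labs correctly", {
  toy <- make_toy_corpus()
  records <- collect_variants(toy$corpus, toy$db)
  expect_equal(nrow(records), 3)
  prom <- records[records$variant_key == toy$expected$prom_key, ]
  expect_equal(prom$n_observations, 3L)
  expect_equal(prom$n_labs, 2L)
  expect_setequal(prom$observations[[1]], c("p04", "p05", "p06"))
  ori <- records[records$variant_key == toy$expected$ori_key, ]
  expect_equal(ori$n_observations, 2L)
  expect_equal(ori$n_labs, 1L)
  cds <- records[records$variant_key == toy$expected$cds_key, ]
  expect_equal(cds$n_observations, 1L)
  # two different substitutions in one part give two records
  set.seed(53)
  part <- rdna(120)
  db <- part_db("pp", category = "promoter", is_cds = FALSE, sequence = part)
  v1 <- substitute_at(part, 30); v2 <- substitute_at(part, 80)
  corpus <- plasmid_corpus(
    c("q1", "q2"), c(paste0(rdna(100), v1, rdna(90)),
                     paste0(rdna(95), v2, rdna(85))), c("la", "lb"))
  recs <- collect_variants(corpus, db)
  expect_equal(nrow(recs), 2)
})

test_that("the same variant twice on one plasmid counts two observations", {
  set.seed(54)
  part <- rdna(150)
  v <- substitute_at(part, 60)
  db <- part_db("dup", category = "terminator", is_cds = FALSE,
                sequence = part)
  corpus <- plasmid_corpus(
    "d1", paste0(rdna(120), v, rdna(200), v, rdna(100)), "lab z")
  recs <- collect_variants(corpus, db)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$n_observations, 2L)
  expect_equal(recs$observations[[1]], c("d1", "d1"))
  expect_equal(recs$n_labs, 1L)
})

test_that("variant keys are invariant to strand and rotation of the plasmid", {
  toy <- make_toy_corpus()
  keys0 <- sort(collect_variants(toy$corpus, toy$db)$variant_key)
  flipped <- toy$corpus
  flipped$sequences[] <- revcomp(flipped$sequences)
  expect_equal(sort(collect_variants(flipped, toy$db)$variant_key), keys0)
  rotated <- toy$corpus
  rotated$sequences[] <- vapply(rotated$sequences,
                                plasmidDS:::rotate_sequence, "", k = 97)
  expect_equal(sort(collect_variants(rotated, toy$db)$variant_key), keys0)
})

test_that("per-category tabulation is consistent with the records", {
  toy <- make_toy_corpus()
  matches <- annotate_corpus(toy$corpus, toy$db)
  records <- collect_variants(toy$corpus, toy$db, matches = matches)
  tab <- tabulate_by_category(records, matches)
  expect_equal(sum(tab$total_variant_observations),
               sum(records$n_observations))
  expect_equal(sum(tab$distinct_variants), nrow(records))
  # ordering: descending by total variant observations
  expect_false(is.unsorted(rev(tab$total_variant_observations)))
  # a category with one variant has a degenerate identity distribution
  cds_row <- tab[tab$category == "CDS", ]
  expect_equal(cds_row$distinct_variants, 1)
  expect_equal(cds_row$identity_min, cds_row$identity_max)
  expect_equal(cds_row$identity_min, 299 / 300)
  # untouched categories report zero variants
  expect_equal(tab$total_variant_observations[tab$category == "ncRNA"], 0)
})
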