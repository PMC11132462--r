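test_that("generation is seed-deterministic down to written bytes", {
  cfg <- small_sim_config(seed = 3)
  sim1 <- generate_corpus(cfg)
  sim2 <- generate_corpus(cfg)
  expect_identical(sim1$corpus$sequences, sim2$corpus$sequences)
  expect_identical(sim1$truth$variant_key, sim2$truth$variant_key)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_corpus(sim1, d1)
  write_synthetic_corpus(sim2, d2)
  expect_identical(readLines(file.path(d1, "corpus.fasta")),
                   readLines(file.path(d2, "corpus.fasta")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  # a different seed changes the corpus
  sim3 <- generate_corpus(small_sim_config(seed = 4))
  expect_false(identical(sim1$corpus$sequences, sim3$corpus$sequences))
})

test_that("corpus size respects the per-lab bounds", {
  cfg <- simulation_config(seed = 1, n_labs = 30L,
                           plasmids_per_lab = c(5L, 10L),
                           planted = list())
  sim <- generate_corpus(cfg)
  expect_gte(sim$corpus$p, 150)
  expect_lte(sim$corpus$p, 300)
  expect_equal(length(unique(sim$corpus$plasmids$lab_id)), 30)
  sizes <- table(sim$corpus$plasmids$lab_id)
  expect_true(all(sizes >= 5 & sizes <= 10))
})

test_that("planted edits are present verbatim in every carrier plasmid", {
  sim <- generate_corpus(small_sim_config(seed = 5))
  canon <- structure(sim$db$sequence, names = sim$db$part_id)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    vseq <- sub("^[^:]+:", "", tr$variant_key)
    # the edit is the single recorded substitution of the canonical part
    expect_equal(nchar(vseq), nchar(canon[[tr$part_id]]))
    diffs <- which(strsplit(vseq, "")[[1]] !=
                     strsplit(canon[[tr$part_id]], "")[[1]])
    expect_equal(diffs, tr$edit_pos)
    expect_equal(substr(canon[[tr$part_id]], tr$edit_pos, tr$edit_pos),
                 tr$ref)
    expect_equal(substr(vseq, tr$edit_pos, tr$edit_pos), tr$alt)
    # each carrier contains the edited part on one strand of its circle
    for (pid in tr$carriers[[1]]) {
      doubled <- paste0(sim$corpus$sequences[[pid]],
                        sim$corpus$sequences[[pid]])
      expect_true(grepl(vseq, doubled, fixed = TRUE) ||
                    grepl(revcomp(vseq), doubled, fixed = TRUE))
    }
  }
})

test_that("convergent lineages are planted in exactly K non-overlapping labs", {
  sim <- generate_corpus(small_sim_config(seed = 6))
  conv <- sim$truth[sim$truth$mode == "convergent", ]
  expect_equal(nrow(conv), 3)
  expect_setequal(conv$expected_origins, c(2L, 3L, 4L))
  for (i in seq_len(nrow(conv))) {
    labs <- conv$carrier_labs[[i]]
    expect_length(labs, conv$expected_origins[i])
    # each carrier belongs to exactly one of the K lineages
    lab_of <- structure(sim$corpus$plasmids$lab_id,
                        names = sim$corpus$plasmids$plasmid_id)
    expect_true(all(lab_of[conv$carriers[[i]]] %in% labs))
  }
  wide <- sim$truth[sim$truth$mode == "widespread", ]
  expect_equal(lengths(wide$carrier_labs), wide$expected_labs)
  drift <- sim$truth[sim$truth$mode == "drift", ]
  expect_true(all(lengths(drift$carrier_labs) == 1))
})

test_that("infeasible planting configurations are rejected", {
  expect_error(
    simulation_config(n_labs = 5L, planted = list(
      planted_variant("widespread", expected_labs = 20L))),
    "demands")
  expect_error(planted_variant("convergent", expected_origins = 1L), "K >= 2")
  expect_error(planted_variant("drift", expected_labs = 3L), "<= 2")
})

test_that("truth_confusion scores perfect and imperfect reports correctly", {
  truth <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    part_id = c("a", "b", "c"), category = "promoter",
    mode = c("widespread", "convergent", "drift"),
    variant_key = c("a:AA", "b:CC", "c:GG"),
    expected_labs = c(20L, 3L, 1L), expected_origins = c(1L, 3L, 1L),
    stringsAsFactors = FALSE)
  reports <- data.frame(
    variant_key = c("a:AA", "b:CC"),
    classification = c("widespread", "convergent"),
    n_clusters = c(NA, 3L), stringsAsFactors = FALSE)
  conf <- truth_confusion(reports, truth)
  expect_equal(conf$recall[conf$mode == "widespread"], 1)
  expect_equal(conf$recall[conf$mode == "convergent"], 1)
  expect_equal(conf$origin_accuracy[conf$mode == "convergent"], 1)
  # drift variant absent from reports counts as a true negative
  expect_equal(conf$recall[conf$mode == "drift"], 1)
  # wrong cluster count costs origin accuracy but not detection
  reports$n_clusters[2] <- 2L
  conf2 <- truth_confusion(reports, truth)
  expect_equal(conf2$origin_accuracy[conf2$mode == "convergent"], 0)
  expect_equal(conf2$n_detected[conf2$mode == "convergent"], 1)
  # colliding keys are a generator bug and must be caught
  truth2 <- truth; truth2$variant_key <- rep("a:AA", 3)
  expect_error(truth_confusion(reports, truth2), "collide")
})
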