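# Synthetic plasmid corpora with known lineage structure and planted part
# variants, so every downstream stage can be checked against ground truth.
#
# Structure emulated:
#   * each lab has a private backbone lineage: a dominant origin of
#     replication, a resistance marker and a terminator separated by
#     lab-unique cloning scars, plus per-plasmid junk insertions at the
#     element junctions.  Contiguous backbone runs are rare in the corpus
#     (only that lab carries them) -- the authorship signal;
#   * expression cassettes (promoter + CDS + terminator, contiguous) are
#     drawn from popularity-weighted catalogs shared by all labs -- the
#     cross-lab common content that makes raw percent identity a poor
#     relatedness measure;
#   * planted variants: drift (one lab's sub-lineage), widespread
#     (inherited by many lab lineages), convergent (the same edit applied
#     independently in K unrelated lineages).  Convergent carriers are
#     built with per-lab-distinct cassette context so the K origins are
#     identifiable by construction.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# clean ORF: ATG + non-stop codons + stop
random_cds <- function(n_nt) {
  stopifnot(n_nt %% 3 == 0, n_nt >= 9)
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  body <- sample(codons, n_nt / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

rand_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

geom_weights <- function(n, ratio) {
  w <- ratio^(seq_len(n) - 1)
  w / sum(w)
}

#' Describe a variant to plant in a synthetic corpus
#'
#' @param mode `"drift"` (one-off change confined to one lab's
#'   sub-lineage), `"widespread"` (inherited by many lab lineages) or
#'   `"convergent"` (the same edit arising independently in K unrelated
#'   lineages).
#' @param part part id to edit (default: assigned automatically from the
#'   generated catalog -- widespread variants take dominant backbone
#'   parts, convergent variants take popular cassette/marker parts, drift
#'   variants take rare parts).
#' @param expected_labs number of labs that must end up carrying the
#'   variant (widespread: >= 20 by default; drift: 1).
#' @param expected_origins number of independent lineages for convergent
#'   variants (K >= 2).
#' @param carriers_per_lab carrier plasmids per carrier lab for
#'   convergent/drift variants.
#' @return object of class `planted_variant`.
#' @export
planted_variant <- function(mode = c("drift", "widespread", "convergent"),
                            part = NULL, expected_labs = NULL,
                            expected_origins = NULL,
                            carriers_per_lab = 2L) {
  mode <- match.arg(mode)
  if (mode == "widespread") {
    expected_labs <- expected_labs %||% 20L
    expected_origins <- 1L
    if (expected_labs < 2) stop("widespread variant needs expected_labs >= 2")
  } else if (mode == "convergent") {
    expected_origins <- expected_origins %||% 2L
    if (expected_origins < 2) stop("convergent variant needs K >= 2")
    expected_labs <- expected_origins
  } else {
    expected_labs <- expected_labs %||% 1L
    if (expected_labs > 2) stop("drift variant is confined to <= 2 labs")
    expected_origins <- 1L
  }
  structure(list(mode = mode, part = part,
                 expected_labs = as.integer(expected_labs),
                 expected_origins = as.integer(expected_origins),
                 carriers_per_lab = as.integer(carriers_per_lab)),
            class = "planted_variant")
}

default_planted <- function() {
  list(planted_variant("widespread", expected_labs = 20L),
       planted_variant("convergent", expected_origins = 2L),
       planted_variant("convergent", expected_origins = 3L),
       planted_variant("convergent", expected_origins = 4L),
       planted_variant("drift"),
       planted_variant("drift"))
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe a mid-sized multi-lab corpus: 25 labs of 8-12
#' plasmids, a dominant origin of replication used by 95% of lab
#' lineages, two resistance markers, and popularity-weighted promoter /
#' CDS / terminator catalogs.  A fixed seed yields a byte-identical
#' corpus.
#'
#' @param seed integer RNG seed; everything the generator draws depends
#'   only on this.
#' @param n_labs number of depositing labs (>= 2).
#' @param plasmids_per_lab integer range `c(lo, hi)`.
#' @param n_parts_per_category named counts of catalog parts; the CDS
#'   count includes the two resistance markers.
#' @param part_reuse_prob probability a lab's backbone uses the dominant
#'   origin rather than a rare one.
#' @param scar_length range of lab-unique scar lengths (nt).
#' @param mutation_rate_drift per-plasmid probability of one random
#'   unplanted part mutation (background noise; set 0 for a noiseless
#'   corpus).
#' @param planted list of [planted_variant()] descriptions.
#' @param cassettes_per_plasmid range of expression cassettes per plasmid.
#' @param junk_per_plasmid number of per-plasmid junk insertions at
#'   backbone junctions (these break the shared backbone into
#'   lab-and-sublineage-specific runs).
#' @param junk_length,spacer_length ranges (nt) for junk insertions and
#'   for the per-plasmid spacers preceding each cassette.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_labs = 25L,
                              plasmids_per_lab = c(8L, 12L),
                              n_parts_per_category = c(
                                "origin of replication" = 3L, "CDS" = 10L,
                                "promoter" = 6L, "terminator" = 4L),
                              part_reuse_prob = 0.95,
                              scar_length = c(15L, 40L),
                              mutation_rate_drift = 0.05,
                              planted = default_planted(),
                              cassettes_per_plasmid = c(1L, 2L),
                              junk_per_plasmid = 2L,
                              junk_length = c(20L, 50L),
                              spacer_length = c(30L, 60L)) {
  stopifnot(n_labs >= 2,
            length(plasmids_per_lab) == 2,
            plasmids_per_lab[1] >= 1,
            plasmids_per_lab[1] <= plasmids_per_lab[2],
            part_reuse_prob >= 0, part_reuse_prob <= 1,
            mutation_rate_drift >= 0, mutation_rate_drift <= 1,
            scar_length[1] <= scar_length[2],
            n_parts_per_category[["CDS"]] >= 3,
            n_parts_per_category[["origin of replication"]] >= 1,
            n_parts_per_category[["promoter"]] >= 1,
            n_parts_per_category[["terminator"]] >= 1)
  for (pv in planted) {
    if (!inherits(pv, "planted_variant")) {
      stop("planted must be a list of planted_variant() objects",
           call. = FALSE)
    }
    if (pv$expected_labs > n_labs) {
      stop("planted ", pv$mode, " variant demands ", pv$expected_labs,
           " labs but the corpus has only ", n_labs, call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_labs = as.integer(n_labs),
                 plasmids_per_lab = as.integer(plasmids_per_lab),
                 n_parts_per_category = n_parts_per_category,
                 part_reuse_prob = part_reuse_prob,
                 scar_length = as.integer(scar_length),
                 mutation_rate_drift = mutation_rate_drift,
                 planted = planted,
                 cassettes_per_plasmid = as.integer(cassettes_per_plasmid),
                 junk_per_plasmid = as.integer(junk_per_plasmid),
                 junk_length = as.integer(junk_length),
                 spacer_length = as.integer(spacer_length)),
            class = "simulation_config")
}

# random substitution away from the part termini (terminal edits would be
# trimmed by local alignment and look like terminal deletions); for CDS,
# require a non-synonymous change that introduces no stop codon
choose_edit <- function(seq, is_cds) {
  len <- nchar(seq)
  stopifnot(len >= 14)
  for (i in seq_len(200)) {
    pos <- sample(seq(7L, len - 6L), 1)
    ref <- substr(seq, pos, pos)
    alt <- sample(setdiff(BASES, ref), 1)
    if (is_cds) {
      cstart <- (pos - 1) %/% 3 * 3 + 1
      codon <- substr(seq, cstart, cstart + 2)
      newcodon <- codon
      substr(newcodon, pos - cstart + 1, pos - cstart + 1) <- alt
      if (newcodon %in% STOP_CODONS) next
      aa_old <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
      aa_new <- as.character(Biostrings::translate(Biostrings::DNAString(newcodon)))
      if (aa_old == aa_new) next
    }
    out <- seq
    substr(out, pos, pos) <- alt
    return(list(pos = pos, ref = ref, alt = alt, seq = out))
  }
  stop("could not find a usable edit position", call. = FALSE)
}

element <- function(kind, seq, part_id = NA_character_) {
  list(kind = kind, seq = seq, part_id = part_id)
}

#' Generate a synthetic plasmid corpus with planted ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `corpus` (a [plasmid_corpus()]), `db` (the part
#'   database, [part_db()] layout) and `truth` (data.frame, one row per
#'   planted variant: variant_id, part_id, category, mode, variant_key,
#'   edit_pos, ref, alt, expected_labs, expected_origins, n_carriers,
#'   plus list-columns `carriers` and `carrier_labs`).
#' @export
generate_corpus <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  npc <- cfg$n_parts_per_category
  n_ori <- npc[["origin of replication"]]
  n_cds <- npc[["CDS"]]; n_pay <- n_cds - 2L
  n_pr <- npc[["promoter"]]; n_tm <- npc[["terminator"]]

  # ---- part catalog -------------------------------------------------------
  ori_ids <- sprintf("ori%02d", seq_len(n_ori))
  mk_ids <- c("mk01", "mk02")
  cd_ids <- sprintf("cd%02d", seq_len(n_pay))
  pr_ids <- sprintf("pr%02d", seq_len(n_pr))
  tm_ids <- sprintf("tm%02d", seq_len(n_tm))
  cds3 <- function(lo, hi) {
    n <- sample(lo:hi, 1); n - n %% 3
  }
  db <- part_db(
    part_id = c(ori_ids, mk_ids, cd_ids, pr_ids, tm_ids),
    category = c(rep("origin of replication", n_ori), rep("CDS", 2 + n_pay),
                 rep("promoter", n_pr), rep("terminator", n_tm)),
    is_cds = c(rep(FALSE, n_ori), rep(TRUE, 2 + n_pay),
               rep(FALSE, n_pr), rep(FALSE, n_tm)),
    sequence = c(
      vapply(ori_ids, function(i) random_seq(sample(580:620, 1)), ""),
      vapply(mk_ids, function(i) random_cds(cds3(450, 600)), ""),
      vapply(cd_ids, function(i) random_cds(cds3(300, 600)), ""),
      vapply(pr_ids, function(i) random_seq(sample(60:120, 1)), ""),
      vapply(tm_ids, function(i) random_seq(sample(45:80, 1)), "")))
  part_seq <- structure(db$sequence, names = db$part_id)
  part_cds <- structure(db$is_cds, names = db$part_id)

  pr_w <- geom_weights(n_pr, 0.85)
  cd_w <- geom_weights(n_pay, 0.85)
  tm_w <- geom_weights(n_tm, 0.85)
  mk_w <- c(0.62, 0.38)

  # ---- assign planted variants to parts ----------------------------------
  widespread_pool <- c(ori_ids[1], mk_ids[1])
  # payload CDS parts first: any lab can carry them (so K independent
  # lineages are always placeable) and they are long enough (>= 300 nt)
  # that a single planted edit keeps canonical copies within the 98%
  # segment-identity window -- the variant-containing segment then counts
  # as common corpus content instead of spuriously linking carrier labs.
  # Short parts (promoters, terminators) sit at the identity granularity
  # boundary: one chance-extension mismatch on a ~70 nt segment already
  # exhausts the 2% budget.
  convergent_pool <- c(cd_ids[seq_len(min(3L, n_pay))], mk_ids[2],
                       if (n_pay >= 4) cd_ids[4])
  drift_pool <- rev(c(pr_ids, cd_ids, tm_ids))
  used <- character(0)
  take_part <- function(pool, mode) {
    avail <- setdiff(pool, used)
    if (length(avail) == 0) {
      stop("no unused catalog part left to plant a ", mode, " variant",
           call. = FALSE)
    }
    avail[1]
  }
  planted <- cfg$planted
  for (i in seq_along(planted)) {
    pv <- planted[[i]]
    if (is.null(pv$part)) {
      pv$part <- switch(pv$mode,
                        widespread = take_part(widespread_pool, pv$mode),
                        convergent = take_part(convergent_pool, pv$mode),
                        drift = take_part(drift_pool, pv$mode))
    }
    if (!pv$part %in% db$part_id) {
      stop("planted variant targets unknown part ", pv$part, call. = FALSE)
    }
    if (pv$part %in% used) {
      stop("two planted variants target the same part ", pv$part,
           call. = FALSE)
    }
    used <- c(used, pv$part)
    edit <- choose_edit(part_seq[[pv$part]], part_cds[[pv$part]])
    pv$edit <- edit
    planted[[i]] <- pv
  }
  planted_parts <- used

  # ---- lab lineages -------------------------------------------------------
  n_labs <- cfg$n_labs
  lab_ids <- sprintf("lab%02d", seq_len(n_labs))
  labs <- lapply(seq_len(n_labs), function(l) {
    ori <- if (n_ori == 1 || stats::runif(1) < cfg$part_reuse_prob)
      ori_ids[1] else sample(ori_ids[-1], 1)
    list(id = lab_ids[l],
         size = rand_range(cfg$plasmids_per_lab),
         ori = ori,
         marker = sample(mk_ids, 1, prob = mk_w),
         term = sample(tm_ids, 1, prob = tm_w),
         scars = replicate(3, random_seq(rand_range(cfg$scar_length))))
  })

  # ---- plasmid skeletons --------------------------------------------------
  make_cassette <- function(pr, cd, tm) {
    list(element("part", part_seq[[pr]], pr),
         element("part", part_seq[[cd]], cd),
         element("part", part_seq[[tm]], tm))
  }
  plasmids <- list()
  counter <- 0L
  for (lab in labs) {
    backbone <- list(
      element("part", part_seq[[lab$ori]], lab$ori),
      element("filler", lab$scars[[1]]),
      element("part", part_seq[[lab$marker]], lab$marker),
      element("filler", lab$scars[[2]]),
      element("part", part_seq[[lab$term]], lab$term),
      element("filler", lab$scars[[3]]))
    for (k in seq_len(lab$size)) {
      counter <- counter + 1L
      elements <- backbone
      # per-plasmid junk at random backbone junctions (sub-lineage signal)
      for (j in seq_len(cfg$junk_per_plasmid)) {
        at <- sample(seq_len(length(elements) + 1L) - 1L, 1)
        junk <- element("filler", random_seq(rand_range(cfg$junk_length)))
        elements <- append(elements, list(junk), after = at)
      }
      n_cas <- rand_range(cfg$cassettes_per_plasmid)
      cassettes <- lapply(seq_len(n_cas), function(x) {
        make_cassette(sample(pr_ids, 1, prob = pr_w),
                      sample(cd_ids, 1, prob = cd_w),
                      sample(tm_ids, 1, prob = tm_w))
      })
      plasmids[[counter]] <- list(
        plasmid_id = sprintf("p%04d", counter),
        lab = lab$id, lab_ori = lab$ori, lab_marker = lab$marker,
        lab_term = lab$term,
        backbone = elements, cassettes = cassettes,
        rotation = NA_integer_)
    }
  }
  n_total <- counter
  lab_of <- vapply(plasmids, `[[`, "", "lab")
  lab_members <- split(seq_len(n_total), lab_of)

  # replace one backbone part element (by part id) with an edited sequence
  override_backbone <- function(pl, part, seq) {
    for (e in seq_along(pl$backbone)) {
      if (identical(pl$backbone[[e]]$part_id, part)) {
        pl$backbone[[e]]$seq <- seq
        pl$backbone[[e]]$edited <- TRUE
        return(pl)
      }
    }
    stop("part ", part, " not on backbone of ", pl$plasmid_id, call. = FALSE)
  }
  # cassette with the rank-r most popular companions; convergent carrier
  # labs get distinct ranks so their cassette context never collides
  forced_cassette <- function(variant_part, variant_seq, rank) {
    cat_of <- db$category[match(variant_part, db$part_id)]
    pr <- pr_ids[min(rank, n_pr)]
    cd <- cd_ids[min(rank, n_pay)]
    tm <- tm_ids[min(rank, n_tm)]
    cas <- make_cassette(pr, cd, tm)
    slot <- switch(cat_of, "promoter" = 1L, "CDS" = 2L, "terminator" = 3L,
                   stop("unsupported cassette category ", cat_of))
    cas[[slot]] <- element("part", variant_seq, variant_part)
    cas[[slot]]$edited <- TRUE
    cas
  }

  # ---- plant variants -----------------------------------------------------
  truth_rows <- list()
  used_carrier <- logical(n_total)  # drift/convergent carriers are disjoint
  backbone_roles <- function(part) {
    if (part %in% ori_ids) return("ori")
    if (part %in% mk_ids) return("marker")
    "payload"
  }
  for (vi in seq_along(planted)) {
    pv <- planted[[vi]]
    part <- pv$part
    vseq <- pv$edit$seq
    role <- backbone_roles(part)
    carriers <- integer(0)
    if (pv$mode == "widespread") {
      if (role == "payload") {
        stop("widespread variants must target a backbone part", call. = FALSE)
      }
      eligible <- which(vapply(labs, function(l) {
        (role == "ori" && l$ori == part) ||
          (role == "marker" && l$marker == part)
      }, NA))
      if (length(eligible) < pv$expected_labs) {
        stop("only ", length(eligible), " labs use part ", part,
             " but the widespread variant demands ", pv$expected_labs,
             call. = FALSE)
      }
      chosen <- sort(sample(eligible, pv$expected_labs))
      for (l in chosen) {
        for (i in lab_members[[lab_ids[l]]]) {
          plasmids[[i]] <- override_backbone(plasmids[[i]], part, vseq)
          carriers <- c(carriers, i)
        }
      }
    } else {
      # convergent / drift: carrier labs with a few carrier plasmids each
      n_lab_needed <- if (pv$mode == "convergent") pv$expected_origins
                      else pv$expected_labs
      eligible <- switch(role,
        ori = which(vapply(labs, function(l) l$ori == part, NA)),
        marker = which(vapply(labs, function(l) l$marker == part, NA)),
        payload = seq_len(n_labs))
      eligible <- eligible[vapply(eligible, function(l)
        sum(!used_carrier[lab_members[[lab_ids[l]]]]) >= pv$carriers_per_lab,
        NA)]
      if (length(eligible) < n_lab_needed) {
        stop("cannot place ", pv$mode, " variant of ", part, ": only ",
             length(eligible), " eligible labs for ", n_lab_needed,
             " required", call. = FALSE)
      }
      chosen <- sort(sample(eligible, n_lab_needed))
      for (k in seq_along(chosen)) {
        members <- lab_members[[lab_ids[chosen[k]]]]
        members <- members[!used_carrier[members]]
        picks <- sort(sample(members, pv$carriers_per_lab))
        used_carrier[picks] <- TRUE
        for (i in picks) {
          if (role == "payload") {
            if (pv$mode == "convergent") {
              # minimal carrier: only the rank-k cassette, so carrier labs
              # share nothing rare across lineages
              plasmids[[i]]$cassettes <- list(forced_cassette(part, vseq, k))
            } else {
              plasmids[[i]]$cassettes <- c(plasmids[[i]]$cassettes,
                                           list(forced_cassette(part, vseq, 1L)))
            }
          } else {
            plasmids[[i]] <- override_backbone(plasmids[[i]], part, vseq)
            if (pv$mode == "convergent") {
              # minimal carrier: a single all-canonical rank-k cassette
              plasmids[[i]]$cassettes <- list(make_cassette(
                pr_ids[min(k, n_pr)], cd_ids[min(k, n_pay)],
                tm_ids[min(k, n_tm)]))
            }
          }
          carriers <- c(carriers, i)
        }
      }
    }
    truth_rows[[vi]] <- data.frame(
      variant_id = sprintf("v%02d", vi), part_id = part,
      category = db$category[match(part, db$part_id)], mode = pv$mode,
      variant_key = paste0(part, ":", vseq),
      edit_pos = pv$edit$pos, ref = pv$edit$ref, alt = pv$edit$alt,
      expected_labs = pv$expected_labs,
      expected_origins = pv$expected_origins,
      n_carriers = length(carriers),
      carriers = I(list(vapply(plasmids[carriers], `[[`, "", "plasmid_id"))),
      carrier_labs = I(list(sort(unique(lab_of[carriers])))),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame()
  if (nrow(truth) && anyDuplicated(truth$variant_key)) {
    stop("planted variant keys collide", call. = FALSE)
  }

  # ---- background drift noise --------------------------------------------
  if (cfg$mutation_rate_drift > 0) {
    for (i in seq_len(n_total)) {
      if (stats::runif(1) >= cfg$mutation_rate_drift) next
      pl <- plasmids[[i]]
      # candidate part elements not involved in any planted variant
      cand <- list()
      for (e in seq_along(pl$backbone)) {
        el <- pl$backbone[[e]]
        if (el$kind == "part" && !isTRUE(el$edited) &&
            !el$part_id %in% planted_parts) {
          cand[[length(cand) + 1L]] <- c("b", e, 0)
        }
      }
      for (ci in seq_along(pl$cassettes)) {
        for (e in seq_along(pl$cassettes[[ci]])) {
          el <- pl$cassettes[[ci]][[e]]
          if (el$kind == "part" && !isTRUE(el$edited) &&
              !el$part_id %in% planted_parts) {
            cand[[length(cand) + 1L]] <- c("c", ci, e)
          }
        }
      }
      if (length(cand) == 0) next
      pick <- cand[[sample.int(length(cand), 1)]]
      if (pick[1] == "b") {
        e <- as.integer(pick[2])
        el <- pl$backbone[[e]]
        edit <- choose_edit(el$seq, part_cds[[el$part_id]])
        pl$backbone[[e]]$seq <- edit$seq
        pl$backbone[[e]]$edited <- TRUE
      } else {
        ci <- as.integer(pick[2]); e <- as.integer(pick[3])
        el <- pl$cassettes[[ci]][[e]]
        edit <- choose_edit(el$seq, part_cds[[el$part_id]])
        pl$cassettes[[ci]][[e]]$seq <- edit$seq
        pl$cassettes[[ci]][[e]]$edited <- TRUE
      }
      plasmids[[i]] <- pl
    }
  }

  # ---- materialize sequences ---------------------------------------------
  seqs <- character(n_total)
  for (i in seq_len(n_total)) {
    pl <- plasmids[[i]]
    pieces <- vapply(pl$backbone, `[[`, "", "seq")
    for (cas in pl$cassettes) {
      pieces <- c(pieces, random_seq(rand_range(cfg$spacer_length)),
                  vapply(cas, `[[`, "", "seq"))
    }
    s <- paste(pieces, collapse = "")
    seqs[i] <- rotate_sequence(s, sample.int(nchar(s), 1) - 1L)
  }
  corpus <- plasmid_corpus(
    vapply(plasmids, `[[`, "", "plasmid_id"), seqs, lab_of, circular = TRUE)
  list(corpus = corpus, db = db, truth = truth)
}

#' Write a synthetic corpus to disk
#'
#' FASTA + metadata TSV for the corpus, FASTA + TSV for the part
#' database, and the planted truth as JSON.
#'
#' @param sim result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_synthetic_corpus <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    sequences = file.path(dir, "corpus.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    parts_fasta = file.path(dir, "parts.fasta"),
    parts_meta = file.path(dir, "parts.tsv"),
    truth = file.path(dir, "truth.json"))
  write_corpus(sim$corpus, paths$sequences, paths$metadata)
  write_part_db(sim$db, paths$parts_fasta, paths$parts_meta)
  truth <- sim$truth
  truth$carriers <- lapply(truth$carriers, identity)
  truth$carrier_labs <- lapply(truth$carrier_labs, identity)
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, digits = NA)
  invisible(paths)
}

#' Compare pipeline output against planted ground truth
#'
#' Per planted mode: how many variants were detected (their key appears
#' among the collected variant records), how many were classified
#' correctly (widespread variants called widespread/both; convergent
#' variants called convergent/both; drift variants kept out of the final
#' list), and for convergent variants how often the predicted number of
#' authorship clusters equals the planted K.
#'
#' @param reports classified cluster reports ([classify_variant()]).
#' @param truth truth data.frame from [generate_corpus()].
#' @return data.frame: mode, n_planted, n_detected, n_classified, recall,
#'   origin_accuracy (NA for non-convergent modes).
#' @export
truth_confusion <- function(reports, truth) {
  if (anyDuplicated(truth$variant_key)) {
    stop("planted variant keys collide", call. = FALSE)
  }
  idx <- match(truth$variant_key, reports$variant_key)
  detected <- !is.na(idx)
  cls <- reports$classification[idx]
  ncl <- reports$n_clusters[idx]
  ok <- logical(nrow(truth))
  origin_exact <- rep(NA, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ok[i] <- switch(truth$mode[i],
      widespread = detected[i] && cls[i] %in% c("widespread", "both"),
      convergent = detected[i] && cls[i] %in% c("convergent", "both"),
      drift = !detected[i] ||
        !cls[i] %in% c("widespread", "convergent", "both"))
    if (truth$mode[i] == "convergent") {
      origin_exact[i] <- detected[i] && !is.na(ncl[i]) &&
        ncl[i] == truth$expected_origins[i]
    }
  }
  rows <- lapply(c("drift", "widespread", "convergent"), function(m) {
    sel <- truth$mode == m
    if (!any(sel)) return(NULL)
    data.frame(mode = m, n_planted = sum(sel),
               n_detected = sum(detected[sel]),
               n_classified = sum(ok[sel]),
               recall = mean(ok[sel]),
               origin_accuracy = if (m == "convergent")
                 mean(origin_exact[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
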