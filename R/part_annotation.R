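# Part annotation: locate canonical parts on plasmids by affine-gap local
# alignment, keep near-full-length matches, and reduce them to variant
# records.
#
# Filters applied to coverage-passing matches, in order:
#   (a) matches with no nucleotide-level differences over the aligned region
#       are canonical, not variants;
#   (b) CDS matches whose alignment omits >= 1 nt at either terminus of the
#       canonical part (3' or 5' deletion) are removed;
#   (c) CDS matches whose translation equals the canonical translation
#       (silent-only changes) are removed.
# What survives is a variant observation.

# map a hit interval on the doubled sequence back to canonical coordinates:
# start in [0, L), end = start + span (may exceed L = wrap-around)
canonical_start <- function(start, L) start %% L

# positions (0-based, mod L) covered by a possibly wrapping interval
circ_positions <- function(start, end, L) {
  if (end <= start) return(integer(0))
  (seq.int(start, end - 1L)) %% L
}

#' Annotate one plasmid against a part database
#'
#' Each part is locally aligned against both strands of the plasmid (the
#' sequence is doubled when circular so matches may wrap around the origin;
#' duplicate hits are collapsed modulo the plasmid length).  Matches
#' covering at least `min_coverage` of the part's database length are
#' returned; overlapping hits to the same part keep only the
#' highest-scoring one (ties: leftmost start, then plus strand).
#'
#' @param sequence plasmid DNA string (uppercase A/C/G/T).
#' @param db part database ([part_db()]).
#' @param min_coverage minimum fraction of the part length covered by the
#'   alignment (default 0.95).
#' @param params [alignment_params()].
#' @param circular is the plasmid circular?
#' @param plasmid_id identifier recorded in the output.
#' @param prescreen skip part/strand combinations that share no exact
#'   16-mer with the plasmid (a performance heuristic; safe whenever true
#'   matches contain a 16 nt exact stretch, which any >= 95%-identity match
#'   of a part longer than ~45 nt does).
#' @return data.frame of feature matches: plasmid_id, part_id, strand,
#'   start, end (0-based half-open; end may exceed the sequence length for
#'   wrap-around matches), q_start, q_end (part coordinates covered),
#'   coverage, nt_identity, aa_identity, score, matched_sequence
#'   (strand-normalized to the part orientation).
#' @export
annotate_plasmid <- function(sequence, db, min_coverage = 0.95,
                             params = alignment_params(), circular = TRUE,
                             plasmid_id = "plasmid", prescreen = TRUE) {
  stopifnot(nrow(db) > 0)
  L <- nchar(sequence)
  subject0 <- if (circular) paste0(sequence, sequence) else sequence
  hits <- list()
  for (k in seq_len(nrow(db))) {
    part <- db$sequence[k]
    Lp <- nchar(part)
    for (strand in c("+", "-")) {
      query <- if (strand == "+") part else revcomp(part)
      if (prescreen && !cpp_shares_kmer(query, subject0, 16L)) next
      sub <- subject0
      for (iter in seq_len(12L)) {
        al <- local_align(query, sub, params)
        if (al$score <= 0) break
        cov <- (al$q_end - al$q_start) / Lp
        if (cov < min_coverage) break
        s_start <- al$s_start
        s_end <- al$s_end
        mseq <- substr(subject0, s_start + 1L, s_end)
        if (strand == "-") mseq <- revcomp(mseq)
        # part coordinates covered, in part orientation
        if (strand == "+") {
          qs <- al$q_start; qe <- al$q_end
        } else {
          qs <- Lp - al$q_end; qe <- Lp - al$q_start
        }
        st <- canonical_start(s_start, L)
        hits[[length(hits) + 1L]] <- data.frame(
          plasmid_id = plasmid_id, part_id = db$part_id[k],
          category = db$category[k], is_cds = db$is_cds[k],
          aa_ok = db$aa_ok[k], strand = strand,
          start = st, end = st + (s_end - s_start),
          q_start = qs, q_end = qe,
          coverage = cov, nt_identity = al$n_match / al$n_cols,
          aa_identity = NA_real_, score = al$score,
          matched_sequence = mseq, stringsAsFactors = FALSE)
        # mask this occurrence (both copies of the doubled sequence)
        for (off in if (circular) c(-L, 0L, L) else 0L) {
          a <- max(0L, s_start + off); b <- min(nchar(sub), s_end + off)
          if (b > a) {
            substr(sub, a + 1L, b) <- strrep("N", b - a)
          }
        }
      }
    }
  }
  if (length(hits) == 0) return(empty_match_df())
  m <- do.call(rbind, hits)
  # collapse duplicates arising from the doubled sequence
  key <- paste(m$part_id, m$strand, m$start, m$end - m$start)
  m <- m[!duplicated(key), , drop = FALSE]
  # per-part overlap resolution: keep best score; ties leftmost, then '+'
  keep <- rep(TRUE, nrow(m))
  for (pid in unique(m$part_id)) {
    idx <- which(m$part_id == pid)
    if (length(idx) < 2) next
    ord <- idx[order(-m$score[idx], m$start[idx],
                     ifelse(m$strand[idx] == "+", 0L, 1L))]
    covered <- integer(0)
    for (i in ord) {
      pos <- circ_positions(m$start[i], m$end[i], L)
      if (any(pos %in% covered)) keep[i] <- FALSE
      else covered <- c(covered, pos)
    }
  }
  m <- m[keep, , drop = FALSE]
  # amino-acid identity for translatable CDS matches of equal aa length
  cds <- which(m$is_cds & m$aa_ok)
  for (i in cds) {
    part <- db$sequence[match(m$part_id[i], db$part_id)]
    if (nchar(m$matched_sequence[i]) %% 3L != 0L) next
    aa_m <- translate_cds(m$matched_sequence[i], m$part_id[i])
    aa_c <- translate_cds(part, m$part_id[i])
    if (!is.na(aa_m) && !is.na(aa_c) && nchar(aa_m) == nchar(aa_c)) {
      v1 <- strsplit(aa_m, "")[[1]]; v2 <- strsplit(aa_c, "")[[1]]
      m$aa_identity[i] <- mean(v1 == v2)
    }
  }
  m <- m[order(m$start, m$part_id, m$strand), , drop = FALSE]
  rownames(m) <- NULL
  m
}

empty_match_df <- function() {
  data.frame(plasmid_id = character(0), part_id = character(0),
             category = character(0), is_cds = logical(0),
             aa_ok = logical(0), strand = character(0),
             start = integer(0), end = integer(0),
             q_start = integer(0), q_end = integer(0),
             coverage = numeric(0), nt_identity = numeric(0),
             aa_identity = numeric(0), score = numeric(0),
             matched_sequence = character(0), stringsAsFactors = FALSE)
}

#' Annotate every plasmid in a corpus
#'
#' @param corpus a [plasmid_corpus()].
#' @param db part database.
#' @inheritParams annotate_plasmid
#' @return data.frame of feature matches across the corpus (see
#'   [annotate_plasmid()]).
#' @export
annotate_corpus <- function(corpus, db, min_coverage = 0.95,
                            params = alignment_params(), prescreen = TRUE) {
  stopifnot(inherits(corpus, "plasmid_corpus"))
  out <- lapply(seq_len(corpus$p), function(i) {
    annotate_plasmid(corpus$sequences[[i]], db,
                     min_coverage = min_coverage, params = params,
                     circular = corpus$plasmids$circular[i],
                     plasmid_id = corpus$plasmids$plasmid_id[i],
                     prescreen = prescreen)
  })
  do.call(rbind, out)
}

#' Filter feature matches down to variant observations
#'
#' Removes canonical matches (no nucleotide difference over the aligned
#' region), CDS matches with a 3' or 5' terminal deletion, and CDS matches
#' whose translation is identical to the canonical translation.  CDS
#' matches whose matched sequence is untranslatable (length not a multiple
#' of 3) are dropped with a warning.
#'
#' @param matches data.frame from [annotate_plasmid()] /
#'   [annotate_corpus()] (already coverage-filtered).
#' @param db part database.
#' @return the subset of `matches` that are variant observations.
#' @export
filter_matches <- function(matches, db) {
  if (nrow(matches) == 0) return(matches)
  part_len <- nchar(db$sequence)[match(matches$part_id, db$part_id)]
  canon <- db$sequence[match(matches$part_id, db$part_id)]
  keep <- rep(TRUE, nrow(matches))
  # (a) no nucleotide-level difference -> canonical, not a variant
  keep[matches$nt_identity >= 1] <- FALSE
  is_cds <- matches$is_cds & matches$aa_ok
  # (b) CDS with a missing terminal base of the canonical part
  term_del <- is_cds & (matches$q_start > 0L | matches$q_end < part_len)
  keep[term_del] <- FALSE
  # (c) CDS whose translation equals the canonical translation
  for (i in which(keep & is_cds)) {
    ms <- matches$matched_sequence[i]
    if (nchar(ms) %% 3L != 0L) {
      warning("variant of CDS part ", matches$part_id[i], " on plasmid ",
              matches$plasmid_id[i],
              " is untranslatable (length not a multiple of 3); dropped",
              call. = FALSE)
      keep[i] <- FALSE
      next
    }
    aa_m <- translate_cds(ms, matches$part_id[i])
    aa_c <- translate_cds(canon[i], matches$part_id[i])
    if (!is.na(aa_m) && !is.na(aa_c) && aa_m == aa_c) keep[i] <- FALSE
  }
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collect variant records across a corpus
#'
#' Annotates all plasmids (unless precomputed matches are supplied),
#' filters to variant observations, and aggregates them into one record
#' per distinct variant sequence.  The variant key is
#' `part_id:matched_sequence` (strand-normalized, uppercase), so the same
#' changed sequence observed anywhere in the corpus lands in one record.
#'
#' @param corpus a [plasmid_corpus()].
#' @param db part database.
#' @param min_coverage,params,prescreen passed to [annotate_corpus()].
#' @param matches optional precomputed match data.frame from
#'   [annotate_corpus()]; supply it to avoid re-annotating.
#' @return data.frame with one row per distinct variant: part_id, category,
#'   variant_key, variant_sequence, n_observations (with multiplicity),
#'   n_labs, nt_identity, plus list-columns `observations` (plasmid ids,
#'   with multiplicity) and `labs`.
#' @export
collect_variants <- function(corpus, db, min_coverage = 0.95,
                             params = alignment_params(), matches = NULL,
                             prescreen = TRUE) {
  stopifnot(inherits(corpus, "plasmid_corpus"))
  if (is.null(matches)) {
    matches <- annotate_corpus(corpus, db, min_coverage = min_coverage,
                               params = params, prescreen = prescreen)
  }
  variants <- filter_matches(matches, db)
  if (nrow(variants) == 0) return(empty_variant_df())
  variants$variant_key <- paste0(variants$part_id, ":",
                                 variants$matched_sequence)
  lab_of <- structure(corpus$plasmids$lab_id,
                      names = corpus$plasmids$plasmid_id)
  keys <- sort(unique(variants$variant_key))
  recs <- lapply(keys, function(k) {
    v <- variants[variants$variant_key == k, , drop = FALSE]
    obs <- sort(v$plasmid_id)
    labs <- sort(unique(unname(lab_of[unique(v$plasmid_id)])))
    data.frame(part_id = v$part_id[1], category = v$category[1],
               variant_key = k, variant_sequence = v$matched_sequence[1],
               n_observations = nrow(v), n_labs = length(labs),
               nt_identity = v$nt_identity[1],
               observations = I(list(obs)), labs = I(list(labs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

empty_variant_df <- function() {
  data.frame(part_id = character(0), category = character(0),
             variant_key = character(0), variant_sequence = character(0),
             n_observations = integer(0), n_labs = integer(0),
             nt_identity = numeric(0),
             observations = I(list()), labs = I(list()),
             stringsAsFactors = FALSE)
}

#' Per-category summary of parts and variants
#'
#' One row per part category: total coverage-passing part matches, total
#' variant observations, number of distinct variant sequences, and the
#' distribution of nucleotide identity between distinct variants and their
#' canonical sequences.  Rows are sorted in descending order of total
#' variant observations.
#'
#' @param records variant records from [collect_variants()].
#' @param matches full match table from [annotate_corpus()] (canonical and
#'   variant matches alike).
#' @param categories category labels to report (default
#'   [part_categories()]).
#' @return data.frame with columns category, total_parts,
#'   total_variant_observations, distinct_variants, identity_min,
#'   identity_q1, identity_median, identity_q3, identity_max.
#' @export
tabulate_by_category <- function(records, matches,
                                 categories = part_categories()) {
  rows <- lapply(categories, function(cat) {
    rc <- records[records$category == cat, , drop = FALSE]
    ids <- rc$nt_identity
    qs <- if (length(ids)) stats::quantile(ids, c(0, .25, .5, .75, 1),
                                           names = FALSE, type = 7)
          else rep(NA_real_, 5)
    data.frame(category = cat,
               total_parts = sum(matches$category == cat),
               total_variant_observations = sum(rc$n_observations),
               distinct_variants = nrow(rc),
               identity_min = qs[1], identity_q1 = qs[2],
               identity_median = qs[3], identity_q3 = qs[4],
               identity_max = qs[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_variant_observations, out$category), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
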