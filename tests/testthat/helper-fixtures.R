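# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; oracles deliberately avoid the package's own
# implementation paths.

BASES4 <- c("A", "C", "G", "T")

rdna <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

rcds <- function(n_codons) {
  codons <- apply(expand.grid(BASES4, BASES4, BASES4), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(codons, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

substitute_at <- function(seq, pos, alt = NULL) {
  ref <- substr(seq, pos, pos)
  if (is.null(alt)) alt <- setdiff(BASES4, ref)[1]
  substr(seq, pos, pos) <- alt
  seq
}

# ---------------------------------------------------------------------------
# union-find connected-component oracle (independent of igraph)

uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  ids <- rownames(adj) %||% as.character(seq_len(n))
  groups <- split(ids, roots)
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, `[`, "", 1))]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# exhaustive dynamic-programming segment oracle (Biostrings Smith-Waterman
# with the same scoring, iterative masking), plus a canonical endpoint
# convention applied to both oracle and production output before comparing:
# seed = leftmost longest exact run, endpoints = outermost positions
# attaining the maximal gapless score (X-drop bounded)

oracle_segments <- function(a, b, params) {
  b5 <- c(BASES4, "N")
  mat <- matrix(params$mismatch, 5, 5, dimnames = list(b5, b5))
  diag(mat)[1:4] <- params$match
  Lb <- nchar(b)
  out <- list()
  for (strand in c("+", "-")) {
    bs <- if (strand == "+") b else revcomp(b)
    aa <- a
    repeat {
      al <- Biostrings::pairwiseAlignment(
        aa, bs, type = "local", substitutionMatrix = mat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend)
      if (Biostrings::score(al) < 2 * params$word_size) break
      ps <- Biostrings::start(Biostrings::pattern(al))
      ss <- Biostrings::start(Biostrings::subject(al))
      pe <- Biostrings::end(Biostrings::pattern(al))
      # split the (possibly gapped) alignment into its gapless pieces; the
      # production decomposition is gapless, so filters apply per piece
      pstr <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
      sstr <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
      ppos <- ps - 1L; spos <- ss - 1L   # 0-based positions consumed next
      piece_a <- ppos; piece_b <- spos; nm <- 0L; ncol_piece <- 0L
      flush <- function() {
        if (ncol_piece > 0) {
          out[[length(out) + 1L]] <<- data.frame(
            strand = strand, a_start = piece_a, a_end = piece_a + ncol_piece,
            bs_start = piece_b, n_match = nm, n_cols = ncol_piece,
            stringsAsFactors = FALSE)
        }
      }
      for (k in seq_along(pstr)) {
        if (pstr[k] == "-" || sstr[k] == "-") {
          flush()
          if (pstr[k] != "-") ppos <- ppos + 1L
          if (sstr[k] != "-") spos <- spos + 1L
          piece_a <- ppos; piece_b <- spos; nm <- 0L; ncol_piece <- 0L
        } else {
          if (ncol_piece == 0L) { piece_a <- ppos; piece_b <- spos }
          nm <- nm + (pstr[k] == sstr[k] && pstr[k] != "N")
          ncol_piece <- ncol_piece + 1L
          ppos <- ppos + 1L; spos <- spos + 1L
        }
      }
      flush()
      substr(aa, ps, pe) <- strrep("N", pe - ps + 1L)
    }
  }
  if (length(out) == 0) return(NULL)
  seg <- do.call(rbind, out)
  len <- seg$a_end - seg$a_start
  identity <- seg$n_match / seg$n_cols
  score <- seg$n_match * params$match +
    (seg$n_cols - seg$n_match) * params$mismatch
  ev <- plasmidDS:::segment_evalue(score, len, 2 * Lb, params)
  seg <- seg[len >= params$word_size & identity >= params$min_identity &
               ev <= params$max_evalue, , drop = FALSE]
  if (nrow(seg) == 0) return(NULL)
  seg
}

# canonical endpoints of one gapless segment in strand space
canon_endpoints <- function(av, bv, a_start, a_end, bs_start, params) {
  d <- a_start - bs_start
  La <- length(av); Lb <- length(bv)
  lo <- max(0L, d); hi <- min(La, Lb + d)
  idx <- seq.int(a_start, a_end - 1L)
  m <- av[idx + 1L] == bv[idx - d + 1L]
  r <- rle(m)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  stopifnot(length(runs) > 0)
  best <- runs[which.max(r$lengths[runs])]  # leftmost longest exact run
  seed_s <- a_start + starts[best] - 1L
  seed_e <- a_start + ends[best]
  sc <- (seed_e - seed_s) * params$match
  e_best <- seed_e; best_sc <- sc
  t <- seed_e
  while (t < hi) {
    sc <- sc + if (av[t + 1L] == bv[t - d + 1L]) params$match else
      params$mismatch
    if (sc >= best_sc) { best_sc <- sc; e_best <- t + 1L }
    else if (best_sc - sc > params$xdrop) break
    t <- t + 1L
  }
  s_best <- seed_s; sc <- best_sc; best2 <- best_sc
  t <- seed_s - 1L
  while (t >= lo) {
    sc <- sc + if (av[t + 1L] == bv[t - d + 1L]) params$match else
      params$mismatch
    if (sc >= best2) { best2 <- sc; s_best <- t }
    else if (best2 - sc > params$xdrop) break
    t <- t - 1L
  }
  c(s_best, e_best, s_best - d)
}

# canonicalize a strand-space segment table (strand, a_start, a_end,
# bs_start), recompute scores over the canonical intervals, then apply the
# same strict greedy non-overlap selection on `a` that the production
# decomposition documents.  Applying one shared boundary convention to both
# the production and the oracle output makes their segment sets directly
# comparable; segment *discovery* remains fully independent.
canon_select_keys <- function(seg, a, b, params) {
  if (is.null(seg) || nrow(seg) == 0) return(character(0))
  av <- strsplit(a, "")[[1]]
  bvs <- list("+" = strsplit(b, "")[[1]],
              "-" = strsplit(revcomp(b), "")[[1]])
  n <- nrow(seg)
  out <- data.frame(strand = seg$strand, a_start = NA_integer_,
                    a_end = NA_integer_, bs_start = NA_integer_,
                    score = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    bv <- bvs[[seg$strand[i]]]
    ce <- canon_endpoints(av, bv, seg$a_start[i], seg$a_end[i],
                          seg$bs_start[i], params)
    idx <- seq.int(ce[1], ce[2] - 1L)
    nm <- sum(av[idx + 1L] == bv[idx - (ce[1] - ce[3]) + 1L])
    out$a_start[i] <- ce[1]; out$a_end[i] <- ce[2]; out$bs_start[i] <- ce[3]
    out$score[i] <- nm * params$match +
      (length(idx) - nm) * params$mismatch
  }
  out <- out[!duplicated(out[, 1:4]), , drop = FALSE]
  ord <- order(-out$score, out$a_start, ifelse(out$strand == "+", 0L, 1L))
  out <- out[ord, , drop = FALSE]
  covered <- integer(0)
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    pos <- seq.int(out$a_start[i], out$a_end[i] - 1L)
    if (!any(pos %in% covered)) {
      keep[i] <- TRUE
      covered <- c(covered, pos)
    }
  }
  out <- out[keep, , drop = FALSE]
  sort(paste(out$strand, out$a_start, out$a_end, out$bs_start))
}

# map production shared_segments() output (forward b coordinates) into
# strand space, then canonicalize
canon_keys_production <- function(seg, a, b, params) {
  if (nrow(seg) == 0) return(character(0))
  Lb <- nchar(b)
  df <- data.frame(
    strand = seg$strand_b, a_start = seg$a_start, a_end = seg$a_end,
    bs_start = ifelse(seg$strand_b == "+", seg$b_start, Lb - seg$b_end),
    stringsAsFactors = FALSE)
  canon_select_keys(df, a, b, params)
}

canon_keys_oracle <- function(seg, a, b, params) {
  if (is.null(seg) || nrow(seg) == 0) return(character(0))
  canon_select_keys(seg[, c("strand", "a_start", "a_end", "bs_start")],
                    a, b, params)
}

# ---------------------------------------------------------------------------
# hand-built 10-plasmid toy corpus exercising every variant filter:
# one silent CDS change, one 5'-truncated CDS, one sub-threshold-coverage
# promoter, three genuine variants, one fully canonical plasmid

make_toy_corpus <- function() {
  withr::with_seed(404, {
    cds <- rcds(100)              # 300 nt
    prom <- rdna(80)
    ori <- rdna(150)
    # silent change: find a codon where a third-position swap is synonymous
    silent <- NA
    for (ci in 2:99) {
      pos <- (ci - 1) * 3 + 3
      for (alt in setdiff(BASES4, substr(cds, pos, pos))) {
        cand <- cds
        substr(cand, pos, pos) <- alt
        aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
        aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(cand)))
        if (aa1 == aa2) { silent <- cand; break }
      }
      if (!is.na(silent)) break
    }
    stopifnot(!is.na(silent))
    # genuine non-synonymous CDS change (2nd codon position, mid-part)
    cds_var <- cds
    pos <- 150 - (150 - 2) %% 3   # a second codon position near the middle
    repeat {
      alt <- sample(setdiff(BASES4, substr(cds, pos, pos)), 1)
      cand <- cds
      substr(cand, pos, pos) <- alt
      aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
      aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(cand)))
      if (aa1 != aa2) { cds_var <- cand; break }
    }
    prom_var <- substitute_at(prom, 40)
    ori_var <- substitute_at(ori, 75)
    cds_5del <- substr(cds, 3, 300)      # missing 2 nt at the 5' end
    prom_low_cov <- substr(prom, 1, 70)  # 70/80 = 0.875 coverage
    # flanks chosen so truncated embeddings cannot extend by chance
    flank <- function(n) rdna(n)
    guard_before <- setdiff(BASES4, substr(cds, 2, 2))[1]
    guard_after <- setdiff(BASES4, substr(prom, 71, 71))[1]
    seqs <- c(
      p01 = paste0(flank(60), silent, flank(70)),
      p02 = paste0(flank(55), guard_before, cds_5del, flank(65)),
      p03 = paste0(flank(50), prom_low_cov, guard_after, flank(75)),
      p04 = paste0(flank(62), prom_var, flank(58)),
      p05 = paste0(flank(57), prom_var, flank(63)),
      p06 = paste0(flank(59), prom_var, flank(61)),
      p07 = paste0(flank(64), ori_var, flank(56)),
      p08 = paste0(flank(66), ori_var, flank(54)),
      p09 = paste0(flank(53), cds_var, flank(67)),
      p10 = paste0(flank(58), cds, flank(52), prom, flank(40)))
    labs <- c("lab a", "lab a", "lab b", "lab a", "lab b", "lab b",
              "lab c", "lab c", "lab c", "lab a")
    db <- part_db(part_id = c("cdsA", "promB", "oriC"),
                  category = c("CDS", "promoter", "origin of replication"),
                  is_cds = c(TRUE, FALSE, FALSE),
                  sequence = c(cds, prom, ori))
    list(corpus = plasmid_corpus(names(seqs), unname(seqs), labs),
         db = db,
         expected = list(
           prom_key = paste0("promB:", prom_var),
           ori_key = paste0("oriC:", ori_var),
           cds_key = paste0("cdsA:", cds_var)))
  })
}

# small noiseless simulation config used by pipeline-level tests
small_sim_config <- function(seed, n_labs = 12L, plasmids_per_lab = c(4L, 6L)) {
  simulation_config(
    seed = seed, n_labs = n_labs, plasmids_per_lab = plasmids_per_lab,
    mutation_rate_drift = 0,
    planted = list(
      planted_variant("widespread", expected_labs = 7L),
      planted_variant("convergent", expected_origins = 2L),
      planted_variant("convergent", expected_origins = 3L),
      planted_variant("convergent", expected_origins = 4L),
      planted_variant("drift"),
      planted_variant("drift")))
}
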