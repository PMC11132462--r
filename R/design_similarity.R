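# The design similarity (DS) score and its empirical calibration.
#
# DS is an inverse-document-frequency-style measure of shared construction
# history: each segment shared by a pair of plasmids is weighted by its
# rarity in the corpus (p / x_i, where x_i is the number of plasmids
# containing the segment and p the corpus size), so ubiquitous backbones
# contribute almost nothing and rare scars dominate.

#' Design similarity score from a segment frequency vector
#'
#' `DS = log(p / x_1 + (sum_{i >= 2} p / x_i) / n)` on the natural-log
#' scale, where `x` is the vector of per-segment plasmid counts sorted
#' ascending (so `x_1` is the rarest shared segment) and `n` the number of
#' shared segments.  The second term is a bonus heuristic that only
#' applies when more than one segment is shared; for `n = 1` the score is
#' exactly `log(p / x_1)`, and a segment present in every plasmid scores 0.
#'
#' @param x integer vector of per-segment plasmid counts (any order;
#'   sorted internally).
#' @param p number of plasmids in the corpus.
#' @return the DS score (numeric scalar).
#' @export
ds_score <- function(x, p) {
  if (length(x) == 0) {
    stop("no shared segments: DS score is undefined for this pair",
         call. = FALSE)
  }
  if (any(x < 1)) stop("segment counts must be >= 1", call. = FALSE)
  if (p < max(x)) stop("p must be >= max(x)", call. = FALSE)
  x <- sort(as.numeric(x))
  n <- length(x)
  extra <- if (n >= 2) sum(p / x[-1]) / n else 0
  log(p / x[1] + extra)
}

#' Pairwise DS score matrix for a set of plasmids
#'
#' Computes the DS score for every unordered pair of the given plasmids.
#' Pairs sharing no segment get `-Inf` (no evidence of relatedness; ranked
#' below every numeric score and below any cutoff).  The diagonal is `NA`
#' (self-pairs are never scored).
#'
#' @param plasmid_ids plasmids to compare (must exist in the corpus).
#' @param corpus a [plasmid_corpus()].
#' @param index a [build_segment_index()] built over the same corpus.
#' @param params [alignment_params()].
#' @return symmetric numeric matrix with plasmid ids as dimnames.
#' @export
pairwise_ds <- function(plasmid_ids, corpus, index,
                        params = alignment_params()) {
  stopifnot(inherits(corpus, "plasmid_corpus"), length(plasmid_ids) >= 2)
  missing <- setdiff(plasmid_ids, corpus$plasmids$plasmid_id)
  if (length(missing)) {
    stop("plasmid(s) not in corpus: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  k <- length(plasmid_ids)
  mat <- matrix(NA_real_, k, k, dimnames = list(plasmid_ids, plasmid_ids))
  circ <- structure(corpus$plasmids$circular,
                    names = corpus$plasmids$plasmid_id)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- plasmid_ids[i]; b <- plasmid_ids[j]
      segs <- shared_segments(corpus$sequences[[a]], corpus$sequences[[b]],
                              params, circ[[a]], circ[[b]])
      fv <- frequency_vector(segs, index, params)
      s <- if (fv$n == 0) -Inf else ds_score(fv$x, corpus$p)
      mat[i, j] <- mat[j, i] <- s
    }
  }
  mat
}

#' Calibrate the DS relatedness cutoff from random cross-lab pairs
#'
#' Samples unordered pairs of plasmids deposited by different labs (pairs
#' from one lab are excluded because they plausibly share construction
#' history), computes their DS scores, and sets the cutoff at the given
#' empirical percentile of the score distribution (nearest-rank, no
#' interpolation).  Downstream, two plasmids are called related only when
#' their score is strictly greater than the cutoff, so by construction
#' about `100 - percentile` percent of the calibration sample would be
#' called related (a controlled false-positive rate).
#'
#' When the population of cross-lab pairs is not larger than `n_pairs`,
#' all pairs are scored exhaustively; otherwise `n_pairs` pairs are drawn
#' uniformly without replacement using `seed`.
#'
#' @param corpus a [plasmid_corpus()] with at least two labs.
#' @param index a [build_segment_index()] over the same corpus.
#' @param n_pairs number of pairs to sample (default 100,000).
#' @param percentile cutoff percentile (default 95).
#' @param seed integer seed for pair sampling.
#' @param params [alignment_params()].
#' @return object of class `ds_calibration`: `cutoff`, `percentile`,
#'   `n_pairs` (pairs actually scored), `seed`, `exhaustive`, `scores`
#'   (the sampled score vector, `-Inf` for pairs sharing nothing), and
#'   `pairs` (data.frame of sampled plasmid id pairs).
#' @export
calibrate_cutoff <- function(corpus, index, n_pairs = 100000L,
                             percentile = 95, seed = 1L,
                             params = alignment_params()) {
  stopifnot(inherits(corpus, "plasmid_corpus"),
            percentile > 0, percentile < 100, n_pairs >= 1)
  labs <- corpus$plasmids$lab_id
  if (length(unique(labs)) < 2) {
    stop("calibration requires plasmids from at least two labs",
         call. = FALSE)
  }
  ids <- corpus$plasmids$plasmid_id
  p <- corpus$p
  # all unordered cross-lab pairs
  idx <- which(upper.tri(matrix(0, p, p)) &
                 outer(labs, labs, `!=`), arr.ind = TRUE)
  npop <- nrow(idx)
  exhaustive <- npop <= n_pairs
  if (exhaustive) {
    take <- seq_len(npop)
    message("cross-lab pair population (", npop, ") <= n_pairs (", n_pairs,
            "): scoring all pairs exhaustively")
  } else {
    take <- withr::with_seed(seed, sample.int(npop, n_pairs))
    take <- sort(take)
  }
  pairs <- data.frame(a = ids[idx[take, 1]], b = ids[idx[take, 2]],
                      stringsAsFactors = FALSE)
  circ <- structure(corpus$plasmids$circular, names = ids)
  scores <- vapply(seq_len(nrow(pairs)), function(r) {
    segs <- shared_segments(corpus$sequences[[pairs$a[r]]],
                            corpus$sequences[[pairs$b[r]]],
                            params, circ[[pairs$a[r]]], circ[[pairs$b[r]]])
    fv <- frequency_vector(segs, index, params)
    if (fv$n == 0) -Inf else ds_score(fv$x, p)
  }, numeric(1))
  cutoff <- nearest_rank_percentile(scores, percentile)
  structure(
    list(cutoff = cutoff, percentile = percentile,
         n_pairs = length(scores), seed = seed, exhaustive = exhaustive,
         scores = scores, pairs = pairs),
    class = "ds_calibration")
}

# nearest-rank percentile of a sample (deterministic, no interpolation)
nearest_rank_percentile <- function(scores, percentile) {
  s <- sort(scores)
  k <- ceiling(percentile / 100 * length(s))
  s[max(1L, k)]
}

#' @export
print.ds_calibration <- function(x, ...) {
  fin <- x$scores[is.finite(x$scores)]
  cat("DS calibration: cutoff ", format(x$cutoff, digits = 4),
      " (", x$percentile, "th percentile of ", x$n_pairs,
      " cross-lab pairs", if (x$exhaustive) ", exhaustive" else "",
      ")\n", sep = "")
  cat("  scores: ", sum(!is.finite(x$scores)), " pairs with no shared",
      " segments; finite range ",
      if (length(fin)) paste0(format(min(fin), digits = 3), " .. ",
                              format(max(fin), digits = 3)) else "none",
      "\n", sep = "")
  invisible(x)
}

#' Binarize a DS score matrix into an adjacency matrix
#'
#' Edge between two plasmids iff their score is strictly greater than the
#' cutoff (a conservative tie policy: scores exactly at the cutoff are not
#' related).  No self-loops.
#'
#' @param mat symmetric score matrix from [pairwise_ds()].
#' @param cutoff numeric cutoff, or a `ds_calibration` object.
#' @return symmetric logical adjacency matrix.
#' @export
binarize <- function(mat, cutoff) {
  if (inherits(cutoff, "ds_calibration")) cutoff <- cutoff$cutoff
  adj <- !is.na(mat) & mat > cutoff
  diag(adj) <- FALSE
  adj
}
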