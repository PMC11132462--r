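# Alignment parameter set and significance machinery shared by the part
# annotator and the segment finder.

#' Alignment parameters for part annotation and segment detection
#'
#' The default scoring scheme (match +2, mismatch -8, gap open 4, gap extend
#' 6, word size 28) is deliberately harsh on mismatches: it favours reporting
#' contiguous segments with few point mutations over long gappy alignments,
#' which is exactly what both the variant caller and the design-similarity
#' segment decomposition need.  A gap of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param match match reward (positive integer).
#' @param mismatch mismatch penalty (negative integer).
#' @param gap_open gap opening penalty (positive; cost, not score).
#' @param gap_extend gap extension penalty per base (positive; cost).
#' @param word_size exact seed length for segment detection.
#' @param min_identity minimum fraction of matching columns for a retained
#'   segment (paper-style retention uses 0.98).
#' @param max_evalue significance threshold for retained segments.
#' @param max_length_diff maximum absolute difference (bp) between a query
#'   segment and a counted containment match.
#' @param xdrop X-drop termination threshold for seed extension.
#' @param karlin_k Karlin-Altschul K constant used in the E-value; an
#'   order-of-magnitude constant (the E filter is far from binding for any
#'   segment that passes the word-size and identity filters, see the methods
#'   vignette).
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2L, mismatch = -8L,
                             gap_open = 4L, gap_extend = 6L,
                             word_size = 28L,
                             min_identity = 0.98,
                             max_evalue = 1e-5,
                             max_length_diff = 10L,
                             xdrop = 100L,
                             karlin_k = 0.1) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            word_size >= 4, word_size <= 32,
            min_identity > 0, min_identity <= 1,
            max_evalue > 0, max_length_diff >= 0, xdrop > 0)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         word_size = as.integer(word_size), min_identity = min_identity,
         max_evalue = max_evalue, max_length_diff = as.integer(max_length_diff),
         xdrop = as.integer(xdrop), karlin_k = karlin_k,
         lambda = karlin_lambda(match, mismatch)),
    class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat("alignment parameters: match ", x$match, ", mismatch ", x$mismatch,
      ", gap open ", x$gap_open, ", gap extend ", x$gap_extend,
      ", word size ", x$word_size, "\n",
      "segment retention: identity >= ", x$min_identity,
      ", E <= ", format(x$max_evalue),
      ", length diff <= ", x$max_length_diff, " bp\n", sep = "")
  invisible(x)
}

#' Karlin-Altschul lambda for an ungapped match/mismatch scheme
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for uniform base
#' composition, i.e. `(1/4) exp(lambda * match) + (3/4) exp(lambda *
#' mismatch) = 1`.
#'
#' @param match match reward.
#' @param mismatch mismatch penalty (negative).
#' @return the positive root lambda.
#' @export
karlin_lambda <- function(match, mismatch) {
  stopifnot(match > 0, mismatch < 0)
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  # positive root: f(0) = 0, f'(0) = expected score < 0 for sane schemes,
  # f -> Inf as l -> Inf
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-6, upper), tol = 1e-12)$root
}

# E-value of an ungapped/lightly-gapped segment of score S for a search of a
# query of length m against a space of n letters.
segment_evalue <- function(score, m, n, params) {
  params$karlin_k * as.numeric(m) * as.numeric(n) *
    exp(-params$lambda * score)
}

#' Best local alignment of two sequences
#'
#' Affine-gap Smith-Waterman (Gotoh) with full traceback, used by the part
#' annotator.  Coordinates are 0-based half-open.
#'
#' @param query,subject DNA strings (uppercase A/C/G/T; `N` is treated as a
#'   universal mismatch and can be used for masking).
#' @param params an [alignment_params()] object.
#' @return a list with `score`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `n_cols` (alignment columns), `n_match`, `q_gap_cols`, `s_gap_cols`,
#'   `identity` (matches / columns, gap columns count as mismatches), or
#'   a list with `score = 0` when no positive-scoring alignment exists.
#' @export
local_align <- function(query, subject, params = alignment_params()) {
  res <- cpp_local_align(query, subject, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
  if (res$score > 0) res$identity <- res$n_match / res$n_cols
  res
}
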