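# Shared-segment detection between plasmid pairs and corpus-wide segment
# frequency queries -- the inputs of the design similarity score.
#
# Segments are found by exact word seeding (default 28-mers) followed by
# X-drop extension under the match/mismatch scoring of alignment_params();
# retained segments must be at least one word long, >= 98% identical and
# pass the E-value threshold.  Circularity is handled by doubling the
# sequences and collapsing duplicate hits modulo length.

count_matches_gapless <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  sum(va == vb & va %in% c("A", "C", "G", "T"))
}

#' Contiguous sequence segments shared by two plasmids
#'
#' @param a,b DNA strings of the two plasmids.
#' @param params [alignment_params()].
#' @param circular_a,circular_b topology of each plasmid.
#' @return data.frame of segment matches: `seq` (the segment as found on
#'   plasmid `a`), `a_start`, `a_end`, `b_start`, `b_end` (0-based
#'   half-open; `*_end` may exceed the respective length for wrap-around
#'   segments), `strand_b`, `length`, `n_match`, `identity`, `score`,
#'   `evalue`.  Overlapping hits are resolved to a maximal non-overlapping
#'   set on plasmid `a` by descending score (ties: leftmost start, then
#'   plus strand).  Empty data.frame when nothing is shared.
#' @export
shared_segments <- function(a, b, params = alignment_params(),
                            circular_a = TRUE, circular_b = TRUE) {
  La <- nchar(a); Lb <- nchar(b)
  a2 <- if (circular_a) paste0(a, a) else a
  b2 <- if (circular_b) paste0(b, b) else b
  L2b <- nchar(b2)
  rows <- list()
  for (strand in c("+", "-")) {
    bstr <- if (strand == "+") b2 else revcomp(b2)
    m <- cpp_find_segments(a2, bstr, params$word_size, params$match,
                           params$mismatch, params$xdrop)
    if (nrow(m) == 0) next
    len <- m[, "a_end"] - m[, "a_start"]
    if (strand == "+") {
      b_start <- m[, "b_start"]
    } else {
      # interval on the reverse strand maps to [L2b - e, L2b - s) forward
      b_start <- L2b - (m[, "b_start"] + len)
    }
    rows[[strand]] <- data.frame(
      a_start = m[, "a_start"], a_end = m[, "a_end"],
      b_start = b_start, strand_b = strand, length = len,
      n_match = m[, "n_match"], score = m[, "score"],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_segment_df())
  seg <- do.call(rbind, rows)
  # keep one representative per position modulo plasmid length
  seg <- seg[seg$a_start < La, , drop = FALSE]
  if (nrow(seg) == 0) return(empty_segment_df())
  key <- paste(seg$a_start, seg$length, seg$strand_b, seg$b_start %% Lb)
  seg <- seg[!duplicated(key), , drop = FALSE]
  # a full-circle match on doubled sequences can exceed one plasmid length
  maxlen <- min(La, Lb)
  over <- seg$length > maxlen
  if (any(over)) {
    for (i in which(over)) {
      extra <- seg$length[i] - maxlen
      seg$a_end[i] <- seg$a_start[i] + maxlen
      if (seg$strand_b[i] == "+") {
        # trimming the right end of a trims the right end of b
      } else {
        # trimming the right end of a trims the left (forward) end of b
        seg$b_start[i] <- seg$b_start[i] + extra
      }
      seg$length[i] <- maxlen
      sa <- substr(a2, seg$a_start[i] + 1L, seg$a_end[i])
      bseq <- get_segment_on_b(b2, seg$b_start[i], maxlen, seg$strand_b[i])
      seg$n_match[i] <- count_matches_gapless(sa, bseq)
      seg$score[i] <- seg$n_match[i] * params$match +
        (maxlen - seg$n_match[i]) * params$mismatch
    }
  }
  seg$b_start <- seg$b_start %% Lb
  seg$b_end <- seg$b_start + seg$length
  seg$identity <- seg$n_match / seg$length
  # significance: query length x subject search space (both strands of the
  # doubled subject)
  seg$evalue <- segment_evalue(seg$score, seg$length, 2 * L2b, params)
  seg <- seg[seg$length >= params$word_size &
               seg$identity >= params$min_identity &
               seg$evalue <= params$max_evalue, , drop = FALSE]
  if (nrow(seg) == 0) return(empty_segment_df())
  # maximal non-overlapping set on plasmid a, greedy by score
  ord <- order(-seg$score, seg$a_start,
               ifelse(seg$strand_b == "+", 0L, 1L))
  seg <- seg[ord, , drop = FALSE]
  covered <- integer(0)
  keep <- logical(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    pos <- circ_positions(seg$a_start[i], seg$a_end[i], La)
    if (!any(pos %in% covered)) {
      keep[i] <- TRUE
      covered <- c(covered, pos)
    }
  }
  seg <- seg[keep, , drop = FALSE]
  seg$seq <- substr(rep(a2, nrow(seg)), seg$a_start + 1L, seg$a_end)
  seg <- seg[order(seg$a_start, seg$strand_b), , drop = FALSE]
  rownames(seg) <- NULL
  seg[, c("seq", "a_start", "a_end", "b_start", "b_end", "strand_b",
          "length", "n_match", "identity", "score", "evalue")]
}

get_segment_on_b <- function(b2, b_start, len, strand) {
  s <- substr(b2, b_start + 1L, b_start + len)
  if (strand == "-") revcomp(s) else s
}

empty_segment_df <- function() {
  data.frame(seq = character(0), a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             strand_b = character(0), length = integer(0),
             n_match = integer(0), identity = numeric(0),
             score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

# --------------------------------------------------------------------------
# corpus index

#' Build a corpus-wide k-mer postings index
#'
#' Exact word -> plasmid-id postings over both strands of all (doubled,
#' when circular) plasmids, used to count how many plasmids contain a
#' segment.  The index holds an external pointer; rebuild it after
#' serialization.
#'
#' @param corpus a [plasmid_corpus()].
#' @param word_size word length (default taken from `params`).
#' @param params [alignment_params()].
#' @return an object of class `segment_index`.
#' @export
build_segment_index <- function(corpus, word_size = NULL,
                                params = alignment_params()) {
  stopifnot(inherits(corpus, "plasmid_corpus"))
  word_size <- word_size %||% params$word_size
  if (word_size < 4) stop("word_size < 4", call. = FALSE)
  fwd <- ifelse(corpus$plasmids$circular,
                paste0(corpus$sequences, corpus$sequences),
                corpus$sequences)
  rev <- revcomp(fwd)
  ptr <- cpp_build_index(fwd, rev, as.integer(word_size))
  structure(
    list(ptr = ptr, word_size = as.integer(word_size),
         plasmid_ids = corpus$plasmids$plasmid_id,
         search_space = 2 * sum(nchar(fwd)),
         cache = new.env(parent = emptyenv())),
    class = "segment_index")
}

#' @export
print.segment_index <- function(x, ...) {
  cat("segment index: ", length(x$plasmid_ids), " plasmids, ",
      cpp_index_size(x$ptr), " distinct ", x$word_size, "-mers\n", sep = "")
  invisible(x)
}

#' Number of plasmids containing a segment
#'
#' Counts distinct plasmids with a containment match of the segment:
#' identity at least `params$min_identity` (unmatched query bases count
#' against identity), matched length within `params$max_length_diff` bp of
#' the segment length, and E-value at most `params$max_evalue`.  Results
#' are memoized per segment sequence inside the index.
#'
#' @param segment segment DNA string (or one row of a [shared_segments()]
#'   data.frame).
#' @param index a [build_segment_index()] object.
#' @param params [alignment_params()].
#' @return integer count of distinct plasmids.
#' @export
segment_frequency <- function(segment, index, params = alignment_params()) {
  if (is.data.frame(segment)) segment <- segment$seq
  stopifnot(length(segment) == 1, inherits(index, "segment_index"))
  hit <- get0(segment, envir = index$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  Lseg <- nchar(segment)
  m <- cpp_segment_matches(index$ptr, segment, params$match, params$mismatch,
                           params$xdrop, params$max_length_diff, 30L)
  n <- 0L
  if (nrow(m) > 0) {
    span <- m[, "sub_span"]
    identity <- m[, "n_match"] / pmax(Lseg, span)
    ev <- segment_evalue(m[, "score"], Lseg, index$search_space, params)
    ok <- abs(span - Lseg) <= params$max_length_diff &
      identity >= params$min_identity & ev <= params$max_evalue
    n <- length(unique(m[ok, "plasmid"]))
  }
  assign(segment, n, envir = index$cache)
  n
}

#' Segment frequency vector for one plasmid pair
#'
#' @param segments data.frame from [shared_segments()] for one pair.
#' @param index a [build_segment_index()] object.
#' @param params [alignment_params()].
#' @return list with `x` (plasmid counts per segment, sorted ascending)
#'   and `n` (number of segments).  `n = 0` means no shared segments: the
#'   pair carries no evidence of relatedness and no DS score is defined.
#' @export
frequency_vector <- function(segments, index, params = alignment_params()) {
  if (nrow(segments) == 0) return(list(x = integer(0), n = 0L))
  x <- vapply(segments$seq, segment_frequency, integer(1),
              index = index, params = params, USE.NAMES = FALSE)
  list(x = sort(x), n = length(x))
}
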