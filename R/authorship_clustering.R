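# Authorship clustering: each variant's carrier plasmids form a graph
# (edges = DS score above the calibrated cutoff); connected components
# ("unlinked subgraphs") estimate how many times the variant arose
# independently.

#' Connected components of a plasmid adjacency matrix
#'
#' @param adjacency symmetric logical adjacency matrix with plasmid ids as
#'   dimnames (no self-loops).
#' @return list of character vectors, one per component; members sorted,
#'   components ordered by their smallest member id.
#' @export
connected_components <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0,
                                           mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  ids <- rownames(adjacency) %||% as.character(seq_len(nrow(adjacency)))
  groups <- unname(split(ids, comp$membership))
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, "", 1))]
}

#' Cluster the carriers of one variant into authorship groups
#'
#' For a variant found in plasmids from two or more depositing labs, all
#' carrier plasmids are compared pairwise with the DS score, the scores
#' are binarized at the calibrated cutoff, and connected components of the
#' resulting graph are counted.  Variants observed more than
#' `max_observations` times are not clustered (the pairwise comparison is
#' the expensive step; such variants can still be classified widespread),
#' and neither are variants confined to a single lab (one lab reusing its
#' own backbone is not evidence of independent origins).  In both cases
#' `skipped_ds` is set and `n_clusters` is reported as missing, never
#' defaulted to 1.
#'
#' @param record one variant record (single row of [collect_variants()]).
#' @param corpus a [plasmid_corpus()].
#' @param index a [build_segment_index()] over the corpus.
#' @param cutoff numeric DS cutoff or a `ds_calibration`.
#' @param max_observations feasibility gate on the number of observations
#'   (default 1205).
#' @param params [alignment_params()].
#' @return one-row data.frame: part_id, category, variant_key,
#'   variant_sequence, n_observations, n_labs, skipped_ds, n_clusters,
#'   classification (NA until [classify_variant()]), plus list-columns
#'   `nodes` (distinct carrier plasmids) and `cluster_members`.
#' @export
cluster_variant <- function(record, corpus, index, cutoff,
                            max_observations = 1205L,
                            params = alignment_params()) {
  stopifnot(nrow(record) == 1)
  if (inherits(cutoff, "ds_calibration")) cutoff <- cutoff$cutoff
  nodes <- sort(unique(record$observations[[1]]))
  skipped <- record$n_observations > max_observations || record$n_labs < 2
  if (skipped) {
    n_clusters <- NA_integer_
    members <- list()
  } else {
    if (length(nodes) < 2) {
      # one plasmid deposited by... impossible here: n_labs >= 2 implies
      # >= 2 distinct plasmids; guard anyway
      members <- list(nodes)
      n_clusters <- 1L
    } else {
      mat <- pairwise_ds(nodes, corpus, index, params)
      adj <- binarize(mat, cutoff)
      members <- connected_components(adj)
      n_clusters <- length(members)
    }
  }
  data.frame(part_id = record$part_id, category = record$category,
             variant_key = record$variant_key,
             variant_sequence = record$variant_sequence,
             n_observations = record$n_observations,
             n_labs = record$n_labs,
             skipped_ds = skipped, n_clusters = n_clusters,
             classification = NA_character_,
             nodes = I(list(nodes)), cluster_members = I(list(members)),
             stringsAsFactors = FALSE)
}

#' Cluster every variant record
#'
#' @param records variant records from [collect_variants()].
#' @inheritParams cluster_variant
#' @return data.frame with one [cluster_variant()] row per record.
#' @export
cluster_variants <- function(records, corpus, index, cutoff,
                             max_observations = 1205L,
                             params = alignment_params()) {
  if (nrow(records) == 0) return(empty_report_df())
  out <- lapply(seq_len(nrow(records)), function(i) {
    cluster_variant(records[i, , drop = FALSE], corpus, index, cutoff,
                    max_observations, params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_report_df <- function() {
  data.frame(part_id = character(0), category = character(0),
             variant_key = character(0), variant_sequence = character(0),
             n_observations = integer(0), n_labs = integer(0),
             skipped_ds = logical(0), n_clusters = integer(0),
             classification = character(0),
             nodes = I(list()), cluster_members = I(list()),
             stringsAsFactors = FALSE)
}
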