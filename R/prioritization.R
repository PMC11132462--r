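# Prioritization: the widespread and recurrence rules, the final merged
# variant list, and the end-to-end pipeline driver.

#' Priority rule configuration
#'
#' Defaults follow the thresholds used on repository-scale corpora: a
#' variant is widespread when found in plasmids from at least 20 labs, and
#' convergent when its carriers split into at least 2 unlinked authorship
#' clusters; pairwise clustering is skipped above 1,205 observations.
#' These are corpus-scale-dependent knobs, not constants; analyses of
#' small corpora should scale `min_labs_widespread` down.
#'
#' @param min_labs_widespread minimum number of distinct depositing labs
#'   for the widespread call.
#' @param min_clusters_convergent minimum number of authorship clusters
#'   for the convergent call.
#' @param max_observations_for_ds feasibility gate on clustering.
#' @return object of class `priority_rules`.
#' @export
priority_rules <- function(min_labs_widespread = 20L,
                           min_clusters_convergent = 2L,
                           max_observations_for_ds = 1205L) {
  stopifnot(min_labs_widespread >= 2, min_clusters_convergent >= 2,
            max_observations_for_ds >= 1)
  structure(list(min_labs_widespread = as.integer(min_labs_widespread),
                 min_clusters_convergent = as.integer(min_clusters_convergent),
                 max_observations_for_ds = as.integer(max_observations_for_ds)),
            class = "priority_rules")
}

#' Classify variants as widespread, convergent, both or neither
#'
#' Widespread: observed in plasmids from at least
#' `min_labs_widespread` distinct labs (counted over all carriers,
#' regardless of cluster membership, so variants skipped by the
#' feasibility gate remain eligible).  Convergent: clustered (not
#' skipped) and split into at least `min_clusters_convergent` unlinked
#' authorship clusters.
#'
#' @param reports data.frame of cluster reports ([cluster_variants()]).
#' @param rules a [priority_rules()] object.
#' @return `reports` with the `classification` column filled in.
#' @export
classify_variant <- function(reports, rules = priority_rules()) {
  if (nrow(reports) == 0) return(reports)
  widespread <- reports$n_labs >= rules$min_labs_widespread
  convergent <- !reports$skipped_ds & !is.na(reports$n_clusters) &
    reports$n_clusters >= rules$min_clusters_convergent
  reports$classification <- ifelse(
    widespread & convergent, "both",
    ifelse(widespread, "widespread",
           ifelse(convergent, "convergent", "neither")))
  reports
}

#' Compile the final prioritized variant list
#'
#' The union of widespread and convergent variants (each variant once;
#' variants qualifying both ways are counted once), in the documented
#' deterministic report order.
#'
#' @param reports classified reports ([classify_variant()]).
#' @param rules a [priority_rules()] object (used to classify if the
#'   `classification` column is still empty).
#' @return subset of `reports` that made the list.
#' @export
compile_final_list <- function(reports, rules = priority_rules()) {
  if (nrow(reports) == 0) return(reports)
  if (anyNA(reports$classification)) {
    reports <- classify_variant(reports, rules)
  }
  out <- reports[reports$classification %in%
                   c("widespread", "convergent", "both"), , drop = FALSE]
  out <- order_reports(out)
  rownames(out) <- NULL
  out
}

#' Run the full variant-prioritization pipeline
#'
#' annotate -> collect variants -> build index -> calibrate cutoff ->
#' cluster each variant -> classify -> write reports.  Reruns with the
#' same inputs and seed are byte-identical.
#'
#' @param corpus a [plasmid_corpus()].
#' @param db part database ([part_db()] / [read_part_db()]).
#' @param rules [priority_rules()].
#' @param params [alignment_params()].
#' @param n_pairs,percentile calibration sample size and percentile.
#' @param seed integer seed for calibration pair sampling.
#' @param min_coverage annotation coverage threshold.
#' @param out_dir optional output directory; when given, writes
#'   `variants.csv` (all variant records), `clusters.csv` (all classified
#'   reports), `final_list.csv` (the prioritized list) and
#'   `manifest.json`.
#' @return (invisibly when writing) list with `matches`, `records`,
#'   `calibration`, `reports`, `final`, `by_category`.
#' @export
run_pipeline <- function(corpus, db, rules = priority_rules(),
                         params = alignment_params(),
                         n_pairs = 100000L, percentile = 95, seed = 1L,
                         min_coverage = 0.95, out_dir = NULL) {
  matches <- annotate_corpus(corpus, db, min_coverage = min_coverage,
                             params = params)
  records <- collect_variants(corpus, db, min_coverage = min_coverage,
                              params = params, matches = matches)
  index <- build_segment_index(corpus, params = params)
  calibration <- calibrate_cutoff(corpus, index, n_pairs = n_pairs,
                                  percentile = percentile, seed = seed,
                                  params = params)
  reports <- cluster_variants(records, corpus, index, calibration,
                              max_observations = rules$max_observations_for_ds,
                              params = params)
  reports <- classify_variant(reports, rules)
  final <- compile_final_list(reports, rules)
  by_category <- tabulate_by_category(records, matches)
  result <- list(matches = matches, records = records,
                 calibration = calibration, reports = reports,
                 final = final, by_category = by_category)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rec_out <- records[, c("part_id", "category", "variant_key",
                           "variant_sequence", "n_observations", "n_labs",
                           "nt_identity")]
    utils::write.csv(rec_out, file.path(out_dir, "variants.csv"),
                     row.names = FALSE)
    write_variant_report(reports, file.path(out_dir, "clusters.csv"))
    write_variant_report(final, file.path(out_dir, "final_list.csv"))
    manifest <- list(
      package = "plasmidDS",
      version = as.character(utils::packageVersion("plasmidDS")),
      seed = seed,
      p = corpus$p,
      n_labs = length(unique(corpus$plasmids$lab_id)),
      min_coverage = min_coverage,
      rules = unclass(rules),
      alignment = unclass(params)[c("match", "mismatch", "gap_open",
                                    "gap_extend", "word_size",
                                    "min_identity", "max_evalue",
                                    "max_length_diff")],
      calibration = list(cutoff = calibration$cutoff,
                         percentile = percentile,
                         n_pairs = calibration$n_pairs,
                         exhaustive = calibration$exhaustive),
      counts = list(matches = nrow(matches),
                    variant_observations = sum(records$n_observations),
                    distinct_variants = nrow(records),
                    clustered = sum(!reports$skipped_ds),
                    widespread = sum(reports$classification %in%
                                       c("widespread", "both")),
                    convergent = sum(reports$classification %in%
                                       c("convergent", "both")),
                    final = nrow(final)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(result))
  }
  result
}
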