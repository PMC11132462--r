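# Corpus, part-database and report input/output.
#
# A corpus is the unit of every analysis: one circular DNA sequence per
# plasmid plus the depositing lab for each plasmid.  Coordinates everywhere
# in the package are 0-based, half-open, on the forward strand of the stored
# (linearized) sequence; `end` may exceed the sequence length to denote a
# feature wrapping around the circular origin, interpreted modulo length.

#' Default genetic part categories
#'
#' The 14 part types used to classify variants.  The set is configurable in
#' [read_part_db()]; these defaults cover the common annotation vocabulary
#' for engineered plasmids.
#'
#' @return character vector of category labels.
#' @export
part_categories <- function() {
  c("CDS", "origin of replication", "promoter", "terminator",
    "ribosome binding site", "protein binding site", "primer binding site",
    "ncRNA", "origin of transfer", "enhancer", "intron", "polyA signal",
    "LTR", "misc feature")
}

# lab identity is an atomic label: exact string match after trimming
# whitespace and case-folding
normalize_lab <- function(x) tolower(trimws(x))

#' Construct a plasmid corpus
#'
#' @param plasmid_id character vector of unique plasmid identifiers.
#' @param sequence character vector of DNA sequences (uppercase A/C/G/T).
#' @param lab_id character vector of depositing-lab labels (normalized by
#'   trimming and case-folding).
#' @param circular logical vector (recycled); engineered plasmids are
#'   circular by default.
#' @return an object of class `plasmid_corpus` with elements `plasmids`
#'   (data.frame: plasmid_id, lab_id, circular, length) and `sequences`
#'   (named character vector); `p` is the number of plasmids.
#' @export
plasmid_corpus <- function(plasmid_id, sequence, lab_id, circular = TRUE) {
  plasmid_id <- as.character(plasmid_id)
  sequence <- as.character(sequence)
  lab_id <- normalize_lab(as.character(lab_id))
  stopifnot(length(plasmid_id) == length(sequence),
            length(plasmid_id) == length(lab_id))
  if (anyDuplicated(plasmid_id)) {
    stop("duplicate plasmid_id: ",
         paste(unique(plasmid_id[duplicated(plasmid_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(lab_id))) {
    stop("empty lab_id for plasmid(s): ",
         paste(plasmid_id[!nzchar(lab_id)], collapse = ", "), call. = FALSE)
  }
  if (any(nchar(sequence) < 1)) {
    stop("empty sequence for plasmid(s): ",
         paste(plasmid_id[nchar(sequence) < 1], collapse = ", "),
         call. = FALSE)
  }
  circular <- rep_len(as.logical(circular), length(plasmid_id))
  names(sequence) <- plasmid_id
  structure(
    list(plasmids = data.frame(plasmid_id = plasmid_id, lab_id = lab_id,
                               circular = circular,
                               length = nchar(sequence),
                               stringsAsFactors = FALSE),
         sequences = sequence,
         p = length(plasmid_id)),
    class = "plasmid_corpus")
}

#' @export
print.plasmid_corpus <- function(x, ...) {
  cat("plasmid corpus: ", x$p, " plasmids from ",
      length(unique(x$plasmids$lab_id)), " labs; lengths ",
      min(x$plasmids$length), "-", max(x$plasmids$length), " bp\n", sep = "")
  invisible(x)
}

# --------------------------------------------------------------------------
# readers

# Minimal GenBank flat-file reader: LOCUS (id + topology) and ORIGIN
# (sequence) only, multiple records per file.
read_genbank_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_start <- grep("^LOCUS", lines)
  if (length(rec_start) == 0) stop("no LOCUS lines in ", path, call. = FALSE)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  recs <- lapply(seq_along(rec_start), function(k) {
    block <- lines[rec_start[k]:rec_end[k]]
    locus <- strsplit(trimws(block[1]), "\\s+")[[1]]
    id <- locus[2]
    circular <- any(grepl("circular", block[1], ignore.case = TRUE))
    oi <- grep("^ORIGIN", block)
    if (length(oi) != 1) stop("record ", id, ": missing ORIGIN", call. = FALSE)
    term <- grep("^//", block)
    term <- term[term > oi][1]
    if (is.na(term)) term <- length(block) + 1L
    seq_lines <- block[(oi + 1L):(term - 1L)]
    seq <- toupper(gsub("[0-9[:space:]]", "", paste(seq_lines, collapse = "")))
    list(id = id, circular = circular, sequence = seq)
  })
  recs
}

read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("plasmid_id", "lab_id")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(md), collapse = ", "), call. = FALSE)
  }
  md
}

#' Read a plasmid corpus from sequence and metadata files
#'
#' @param sequence_path FASTA (one record per plasmid) or GenBank flat file.
#'   Format is chosen by extension (`.gb`, `.gbk`, `.genbank` for GenBank)
#'   unless `format` is given.
#' @param metadata_path tab-delimited table with header columns
#'   `plasmid_id` and `lab_id` (extra columns are ignored).
#' @param format `"auto"`, `"fasta"` or `"genbank"`.
#' @param circular_default topology assigned to FASTA records (GenBank
#'   records carry their own topology on the LOCUS line).
#' @param on_ambiguous passed to [normalize_sequence()].
#' @return a [plasmid_corpus()].
#' @export
read_corpus <- function(sequence_path, metadata_path,
                        format = c("auto", "fasta", "genbank"),
                        circular_default = TRUE,
                        on_ambiguous = c("error", "replace")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", sequence_path,
                        ignore.case = TRUE)) "genbank" else "fasta"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(sequence_path)
    ids <- sub("\\s.*$", "", names(seqs))
    sequence <- as.character(seqs)
    circular <- rep(circular_default, length(ids))
  } else {
    recs <- read_genbank_records(sequence_path)
    ids <- vapply(recs, `[[`, "", "id")
    sequence <- vapply(recs, `[[`, "", "sequence")
    circular <- vapply(recs, `[[`, NA, "circular")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate plasmid_id in ", sequence_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sequence <- normalize_sequence(sequence, on_ambiguous)
  md <- read_metadata(metadata_path)
  missing <- setdiff(ids, md$plasmid_id)
  if (length(missing) > 0) {
    stop("plasmid(s) missing from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lab <- md$lab_id[match(ids, md$plasmid_id)]
  plasmid_corpus(ids, sequence, lab, circular)
}

#' Write a corpus as FASTA plus metadata TSV
#'
#' @param corpus a [plasmid_corpus()].
#' @param sequence_path output FASTA path.
#' @param metadata_path output TSV path (`plasmid_id`, `lab_id`).
#' @return invisibly, the corpus.
#' @export
write_corpus <- function(corpus, sequence_path, metadata_path) {
  stopifnot(inherits(corpus, "plasmid_corpus"))
  dss <- Biostrings::DNAStringSet(corpus$sequences)
  Biostrings::writeXStringSet(dss, sequence_path)
  md <- corpus$plasmids[, c("plasmid_id", "lab_id")]
  utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(corpus)
}

#' Read a canonical genetic part database
#'
#' Parts are given as a FASTA of canonical sequences plus a tab-delimited
#' sidecar with columns `part_id`, `name`, `category`, `is_cds`.
#'
#' @param fasta_path FASTA of part sequences; record ids must match
#'   `part_id` in the sidecar.
#' @param meta_path sidecar TSV.
#' @param categories allowed category labels (default [part_categories()]).
#' @return data.frame with columns part_id, name, category, is_cds,
#'   sequence, aa_ok (FALSE when a CDS length is not a multiple of 3, in
#'   which case amino-acid-level comparisons are skipped for that part).
#' @export
read_part_db <- function(fasta_path, meta_path,
                         categories = part_categories()) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  md <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("part_id", "name", "category", "is_cds")
  if (!all(need %in% names(md))) {
    stop("part metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(ids, md$part_id)
  if (length(missing) > 0) {
    stop("part(s) missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  md <- md[match(ids, md$part_id), ]
  bad <- !md$category %in% categories
  if (any(bad)) {
    stop("unknown part category: ",
         paste(unique(md$category[bad]), collapse = ", "),
         "; valid categories: ", paste(categories, collapse = ", "),
         call. = FALSE)
  }
  db <- part_db(part_id = md$part_id, name = md$name, category = md$category,
                is_cds = as.logical(md$is_cds),
                sequence = normalize_sequence(as.character(seqs)))
  db
}

#' Construct a part database in code
#'
#' @param part_id,name,category,is_cds,sequence parallel vectors describing
#'   each canonical part.
#' @return data.frame as documented in [read_part_db()].
#' @export
part_db <- function(part_id, name = part_id, category, is_cds, sequence) {
  sequence <- as.character(sequence)
  if (any(nchar(sequence) < 1)) {
    stop("empty part sequence: ",
         paste(part_id[nchar(sequence) < 1], collapse = ", "), call. = FALSE)
  }
  is_cds <- as.logical(is_cds)
  aa_ok <- !is_cds | (nchar(sequence) %% 3L == 0L)
  if (any(!aa_ok)) {
    warning("CDS part(s) with length not divisible by 3: ",
            paste(part_id[!aa_ok], collapse = ", "),
            "; amino-acid comparisons disabled for these parts",
            call. = FALSE)
  }
  data.frame(part_id = as.character(part_id), name = as.character(name),
             category = as.character(category), is_cds = is_cds,
             sequence = sequence, aa_ok = aa_ok, stringsAsFactors = FALSE)
}

#' Write a part database as FASTA plus sidecar TSV
#'
#' @param db part database data.frame ([part_db()]).
#' @param fasta_path,meta_path output paths.
#' @return invisibly, `db`.
#' @export
write_part_db <- function(db, fasta_path, meta_path) {
  dss <- Biostrings::DNAStringSet(structure(db$sequence, names = db$part_id))
  Biostrings::writeXStringSet(dss, fasta_path)
  utils::write.table(db[, c("part_id", "name", "category", "is_cds")],
                     meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(db)
}

# --------------------------------------------------------------------------
# report writer

# documented row order for all variant reports
order_reports <- function(df) {
  class_rank <- match(df$classification,
                      c("both", "widespread", "convergent", "neither"))
  class_rank[is.na(class_rank)] <- 5L
  df[order(class_rank, -df$n_labs, df$variant_key), , drop = FALSE]
}

#' Write the final variant report as CSV
#'
#' One row per variant with its counts, cluster number and classification.
#' Rows are sorted by classification (both, widespread, convergent,
#' neither), then by number of labs (descending), then by variant key, so
#' output is deterministic.
#'
#' @param reports data.frame of variant cluster reports
#'   ([cluster_variant()] rows, after [classify_variant()]).
#' @param path output CSV path.
#' @return invisibly, the data.frame actually written.
#' @export
write_variant_report <- function(reports, path) {
  cols <- c("part_id", "category", "variant_key", "n_observations",
            "n_labs", "n_clusters", "classification", "variant_sequence")
  if (nrow(reports) == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
  } else {
    out <- order_reports(reports)[, cols, drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(out)
}
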