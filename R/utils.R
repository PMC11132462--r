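# Small shared helpers: sequence normalization, reverse complement,
# translation.  All sequences inside the package are plain uppercase
# character strings over A/C/G/T; Biostrings does the heavy lifting.

IUPAC_FALLBACK <- c(
  R = "A", Y = "C", S = "C", W = "A", K = "G", M = "A",
  B = "C", D = "A", H = "A", V = "A", N = "A", U = "T"
)

#' Normalize a DNA sequence to uppercase A/C/G/T
#'
#' @param x character vector of DNA sequences.
#' @param on_ambiguous what to do with IUPAC ambiguity codes: `"error"`
#'   (default) rejects them, `"replace"` substitutes each code with a fixed
#'   representative base (deterministic).
#' @return character vector of normalized sequences.
#' @export
normalize_sequence <- function(x, on_ambiguous = c("error", "replace")) {
  on_ambiguous <- match.arg(on_ambiguous)
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    if (on_ambiguous == "error") {
      chars <- unique(unlist(strsplit(gsub("[ACGT]", "", x[bad]), "")))
      stop("non-ACGT characters in sequence(s): ",
           paste(chars, collapse = ", "),
           " (set on_ambiguous = \"replace\" to substitute)", call. = FALSE)
    }
    x[bad] <- vapply(x[bad], function(s) {
      ch <- strsplit(s, "")[[1]]
      amb <- !ch %in% c("A", "C", "G", "T")
      repl <- IUPAC_FALLBACK[ch[amb]]
      if (anyNA(repl)) {
        stop("unrecognized sequence character(s): ",
             paste(unique(ch[amb][is.na(repl)]), collapse = ", "),
             call. = FALSE)
      }
      ch[amb] <- repl
      paste(ch, collapse = "")
    }, character(1))
  }
  x
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- cpp_revcomp(toupper(x))
  names(out) <- names(x)
  out
}

# Translate a coding sequence; returns NA (with a warning naming `label`)
# when the length is not a multiple of 3.
translate_cds <- function(x, label = "sequence") {
  if (nchar(x) %% 3L != 0L) {
    warning("length of ", label, " is not a multiple of 3; ",
            "amino-acid comparison skipped", call. = FALSE)
    return(NA_character_)
  }
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X"))
}

# rotate a circular sequence so that it starts at 0-based offset `k`
rotate_sequence <- function(x, k) {
  n <- nchar(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  paste0(substr(x, k + 1L, n), substr(x, 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
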