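Package: plasmidDS
Title: Widespread and Recurrent Genetic Part Variants in Engineered Plasmid Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects variants of canonical genetic parts (origins of replication,
    resistance markers, promoters, and other common elements) across a corpus of
    engineered plasmid sequences and decides which variants deserve cataloguing.
    Plasmids are annotated against a user-supplied part database by affine-gap
    local alignment; non-canonical part occurrences are filtered and aggregated
    into variant records. Plasmids sharing a variant are then compared with an
    inverse-document-frequency-inspired design similarity (DS) score computed
    from shared sequence segments weighted by their rarity in the whole corpus.
    A relatedness cutoff is calibrated empirically from random pairs of plasmids
    deposited by different labs, and connected components of the cutoff-binarized
    plasmid graph estimate how many times a variant arose independently. Variants
    observed in many labs (widespread) or in several unlinked authorship clusters
    (convergent) are compiled into a prioritized report. Includes a synthetic
    plasmid corpus generator with planted ground-truth variants for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
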