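# plasmidDS

Identify genetic part variants worth cataloguing in a corpus of engineered
plasmid sequences: variants that are **widespread** (carried by plasmids
deposited by many independent labs) and variants that are **recurrent**
(the same change arose in two or more unrelated plasmid lineages through
convergent engineering or evolution).

## Who this is for

Anyone curating plasmid annotation databases or analysing a repository of
fully sequenced engineered plasmids. Annotation pipelines silently
tolerate small deviations from canonical part sequences; most of those
deviations are one-off drift fixed by cloning bottlenecks, but some have
spread across the community or arisen repeatedly — and those are the ones
likely to change how an origin, marker, promoter or protein actually
behaves.

## The method

1. **Annotate** every plasmid against a database of canonical parts by
   affine-gap local alignment, keeping matches covering ≥ 95% of the
   part. Matches identical to the canonical sequence at the nucleotide
   level, CDS matches with 3′/5′ terminal deletions, and CDS matches with
   only silent changes are filtered out; what remains are variant
   observations, aggregated by distinct variant sequence.
2. **Score relatedness** of plasmid pairs carrying the same variant with
   a design similarity (DS) score inspired by inverse document frequency.
   Shared sequence segments (found by a 28-mer seed-and-extend search
   under match +2 / mismatch −8 scoring, kept at ≥ 98% identity and
   E ≤ 1e−5) are weighted by rarity: with `x` the per-segment corpus
   plasmid counts sorted ascending and `p` the corpus size,

   ```
   DS = log( p / x[1] + ( Σ_{i≥2} p / x[i] ) / n )
   ```

   so a ubiquitous backbone contributes nothing and a rare cloning scar
   dominates.
3. **Calibrate** a relatedness cutoff as the 95th percentile of DS scores
   of random plasmid pairs from different labs — a designed 5%
   false-positive rate.
4. **Cluster** each variant's carriers: binarize pairwise scores at the
   cutoff and count connected components ("authorship clusters"). Two or
   more components mean independent origins.
5. **Prioritize**: variants in ≥ 20 labs are widespread; variants in ≥ 2
   clusters are convergent; the final list is their union.

A synthetic corpus generator with planted ground truth (drift,
widespread, and convergent variants in K independent lineages) backs the
test suite end to end. See the methods vignette
(`vignettes/design-similarity-methods.Rmd`) for the model, parameter and
numerical conventions, and known limitations.

## Worked example

Reading the bundled three-plasmid example corpus and calling variants:

```r
library(plasmidDS)
corpus <- read_corpus(
  system.file("extdata", "example_corpus.fasta", package = "plasmidDS"),
  system.file("extdata", "example_metadata.tsv", package = "plasmidDS"))
db <- read_part_db(
  system.file("extdata", "example_parts.fasta", package = "plasmidDS"),
  system.file("extdata", "example_parts.tsv", package = "plasmidDS"))
corpus
#> plasmid corpus: 3 plasmids from 2 labs; lengths 441-456 bp
collect_variants(corpus, db)[, c("part_id", "category", "n_observations",
                                 "n_labs", "nt_identity")]
#>   part_id              category n_observations n_labs nt_identity
#> 1   oriEx origin of replication              1      1   0.9933333
#> 2  promEx              promoter              1      1   0.9875000
```

Two plasmids carry single-substitution variants of the example origin
(149/150 identical bases) and promoter (79/80); each is currently seen in
one lab — candidate drift, nothing to prioritize yet.

The full pipeline on a generated corpus with planted truth, using
thresholds scaled to the corpus size (widespread = ≥ 5 of 12 labs):

```r
cfg <- simulation_config(
  seed = 42, n_labs = 12, plasmids_per_lab = c(4L, 6L),
  mutation_rate_drift = 0,
  planted = list(
    planted_variant("widespread", expected_labs = 7L),
    planted_variant("convergent", expected_origins = 3L),
    planted_variant("drift")))
sim <- generate_corpus(cfg)
res <- run_pipeline(sim$corpus, sim$db,
                    rules = priority_rules(min_labs_widespread = 5L),
                    n_pairs = 2000L, seed = 42)
res$calibration
#> DS calibration: cutoff 3.023 (95th percentile of 1647 cross-lab pairs, exhaustive)
#>   scores: 1 pairs with no shared segments; finite range 0.087 .. 3.63
res$reports[, c("part_id", "n_observations", "n_labs", "n_clusters",
                "classification")]
#>   part_id n_observations n_labs n_clusters classification
#> 1    cd01              6      3          3     convergent
#> 2   ori01             35      7          1     widespread
#> 3    tm04              2      1         NA        neither
truth_confusion(res$reports, sim$truth)
#>         mode n_planted n_detected n_classified recall origin_accuracy
#> 1      drift         1          1            1      1              NA
#> 2 widespread         1          1            1      1               NA
#> 3 convergent         1          1            1      1               1
```

The planted origin-of-replication variant inherited by 7 lab lineages is
called widespread; the CDS variant planted independently into 3 unrelated
lineages forms exactly 3 authorship clusters and is called convergent;
the drift variant stays in one lab and is left out. `res$final` /
`final_list.csv` contain the union of widespread and convergent variants
in a deterministic order.

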