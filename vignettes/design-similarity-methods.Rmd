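---
title: "Detecting widespread and recurrent genetic part variants with design similarity scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting widespread and recurrent genetic part variants with design similarity scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidDS)
```

## The problem

Engineered plasmids accumulate small sequence changes in their genetic
parts — origins of replication, resistance markers, promoters, coding
sequences — through both deliberate editing and spontaneous mutation during
cloning and propagation. When a repository-scale corpus of fully sequenced
plasmids is annotated against a database of canonical parts, a large
fraction of part occurrences differ slightly from their reference
sequences. Most of these variants are one-off drift: a mutation fixed by
the extreme population bottlenecks of transformation and colony picking,
then copied through one lab's plasmid lineage. Those are not worth
cataloguing. Two kinds are: variants that have spread to many independent
labs, and variants that arose more than once in unrelated plasmid lineages
(convergent engineering or evolution). Both are disproportionately likely
to change part function, and both belong in annotation databases.

The hard part is the second kind. Deciding that two plasmids carrying the
same variant are *unrelated* requires a relatedness measure that is not
fooled by the enormous amount of sequence every pair of engineered plasmids
shares. Raw percent identity fails in both directions: two unrelated
plasmids that both use a dominant origin and a common resistance marker can
be mostly identical, while two sibling plasmids from one lab can differ in
most of their length yet share a telltale cloning scar.

## The design similarity score

plasmidDS treats plasmids as authored documents. Shared sequence segments
between a pair of plasmids are the shared phrases; each segment is weighted
by its rarity in the whole corpus, in the spirit of inverse document
frequency. For a pair of plasmids, let `x` be the vector of per-segment
plasmid counts (how many of the `p` corpus plasmids contain each shared
segment), sorted ascending so `x[1]` belongs to the rarest segment. The
design similarity score is

    DS = log( p / x[1] + ( sum_{i >= 2} p / x[i] ) / n )

on the natural-log scale, with `n` the number of shared segments. The
first term is the inverse document frequency of the rarest shared segment;
the second is a bonus that only exists when more than one segment is
shared. A segment present in every plasmid contributes `log(1) = 0` — a
ubiquitous backbone is no evidence of shared authorship — while a scar
present in only two plasmids of a 50,000-plasmid corpus contributes about
`log(25000) ≈ 10`.

Two reading ambiguities in this formula are resolved as package
conventions: the log is natural (any base would only rescale both the
scores and the empirically calibrated cutoff, so the choice is internally
consistent), and the `1/n` divides only the `i >= 2` sum, so that the
bonus term vanishes when a single segment is shared. The segment that
contains the variant part itself is *not* excluded from `x`; since the
frequency query tolerates 2% divergence, a variant of a popular part is
counted as common content (see "Why convergent variants must live on long
parts" below).

### Segment detection

Shared segments are found with an exact-word seed-and-extend search:
28-mer seeds, gapless X-drop extension under match +2 / mismatch −8, and
endpoints placed at the outermost positions attaining the maximal segment
score. The scoring family (match +2, mismatch −8, gap open 4, gap extend
6, word size 28) deliberately punishes mismatches far more than typical
defaults: the intended unit of evidence is a contiguous stretch with at
most a few point mutations, not a long gappy alignment. Retained segments
must be at least one word long, at least 98% identical, and significant at
`E <= 1e-5`. Overlapping hits are reduced to a maximal non-overlapping set
on the query plasmid, greedily by score (ties: leftmost, then plus
strand), which makes the decomposition deterministic. Circular topology is
handled by doubling sequences and collapsing duplicate hits modulo length,
so segments may wrap the linearization origin. Because mismatches (−8)
are cheaper than any gap (open 4 + extend 6 per base), substitution-level
divergence produces gapless segments; the test suite verifies the
production finder against an independent exhaustive dynamic-programming
oracle (Biostrings Smith–Waterman under identical scoring and filters) on
hundreds of seeded random pairs with planted exact and 1–2% divergent
blocks.

The E-value uses the Karlin–Altschul form `E = K·m·n·exp(−λS)`. λ is
solved numerically for the +2/−8 scheme under uniform base composition
(λ ≈ 0.692); `K` is an order-of-magnitude constant (default 0.1) exposed
as a parameter rather than derived exactly, because the filter is nowhere
near binding: any segment passing the word-size and identity filters
scores at least 56, giving `E ≈ 1e-10` even for `K = 1` at the corpus
sizes involved. The search-space term `n` is the doubled subject length
times two strands for pair searches, and the total doubled corpus length
for frequency queries.

### Segment frequency

Counting how many plasmids contain a segment uses a corpus-wide postings
index (28-mer → plasmid/strand/position) so that candidate plasmids are
extended directly at seed positions instead of being rescanned. A plasmid
counts when it has a containment match of the segment with at least 98%
identity (unmatched query bases count against identity), matched length
within 10 bp of the segment length, and a passing E-value; colinear
gapless runs separated by indels of at most 10 bp are chained before the
test. Each plasmid counts at most once, however many times the segment
occurs in it. Results are memoized per segment string, which matters
because the same backbone-derived segments recur across thousands of
pairs.

## Calibrating the relatedness cutoff

There is no absolute scale on which a DS score means "related", so the
cutoff is calibrated empirically: sample random unordered pairs of
plasmids deposited by *different* labs (same-lab pairs plausibly share
construction history and are excluded), score them, and take the 95th
percentile of the sample as the cutoff. Downstream, an edge requires a
score strictly greater than the cutoff, so by construction about 5% of
unrelated-by-assumption pairs would be linked — a designed false-positive
rate. The percentile is nearest-rank on the sorted sample (no
interpolation) and pairs sharing no segment at all carry a sentinel below
every numeric score (conceptually −∞), never an arbitrary finite value:
absence of evidence must not be able to cross any cutoff. When the
population of cross-lab pairs is smaller than the requested sample, all
pairs are scored exhaustively. The default sample size follows
repository-scale practice (100,000 pairs); desk-scale analyses and the
package's own tests use 10,000 and state so.

## Clustering and classification

For each variant found in two or more labs and observed at most 1,205
times (the feasibility gate on the quadratic pairwise step — such variants
remain eligible for the widespread call), all carrier plasmids are
compared pairwise, scores are binarized at the cutoff, and connected
components of the resulting graph are counted. Each component is an
authorship cluster: a set of plasmids that plausibly inherited the variant
from a common construction history. Two or more components imply the
variant arose independently at least that many times. Variants confined
to one lab are not clustered (a lab recycling its own backbone is not
evidence of independent origins); their cluster count is reported as
missing, never defaulted to 1, to avoid silently under-calling
convergence.

Classification is then rule-based: *widespread* if carried by at least
`min_labs_widespread` distinct labs (default 20, counted over all
carriers regardless of clustering); *convergent* if clustered into at
least `min_clusters_convergent` components (default 2); *both* or
*neither* accordingly. The final list is the union of widespread and
convergent variants, each counted once. The lab/observation thresholds
are corpus-scale-dependent configuration, not constants: analyses of
small corpora should scale them down (the package tests use a 5-lab
widespread threshold on ~50-plasmid corpora).

## Part annotation and variant filters

Plasmids are annotated by affine-gap local alignment (Gotoh) of every
database part against both strands of the doubled sequence, with iterative
masking to recover multiple occurrences. A match must cover at least 95%
of the part's database length; coverage is the fraction of part positions
consumed by the alignment, so terminal unaligned bases count against it.
Within the coverage-passing matches, variants are what remains after three
filters:

1. matches with no nucleotide-level difference over the aligned region
   are canonical;
2. CDS matches missing one or more bases at either terminus of the
   canonical part (3′ or 5′ deletions) are removed — a truncation is an
   annotation boundary problem, not a sequence variant; internal
   deletions remain variants;
3. CDS matches whose translation equals the canonical translation
   (silent-only changes) are removed. A CDS match whose matched sequence
   is untranslatable (length not a multiple of 3) is dropped with a
   warning, as is amino-acid comparison for any database part whose
   canonical CDS length is not a multiple of 3.

Nucleotide identity is matches over alignment columns, with gap columns
counting as mismatches. The variant key is the part id plus the
strand-normalized matched sequence, so identical changes observed
anywhere in the corpus aggregate into one record.

## The synthetic corpus generator

Real repository corpora cannot be redistributed, so every downstream
stage is validated on generated corpora with planted ground truth. The
generator emulates the structural features the method actually relies on:

* **Lab lineages.** Each lab owns a backbone: a dominant origin of
  replication (used by 95% of lab lineages, mirroring how thoroughly a
  single origin dominates real corpora), one of two resistance markers
  (62/38), a terminator, and three lab-unique scars of 15–40 nt between
  them. Each plasmid additionally receives two unique junk insertions at
  backbone junctions, so same-lab pairs share several contiguous
  backbone runs found only in that lab — the authorship signal.
* **Common content.** Every plasmid carries one or two expression
  cassettes (promoter + CDS + terminator, contiguous) drawn from
  popularity-weighted catalogs (geometric weights, ratio 0.85), preceded
  by per-plasmid spacers. Cross-lab pairs therefore share abundant
  common content — exactly the trap that defeats percent identity — and
  occasionally share rarer cassette combinations, which is what gives
  the cross-lab score distribution its upper tail.
* **Planted variants.** Drift variants are confined to a couple of
  plasmids in one lab. Widespread variants replace a dominant backbone
  part across a configured number of lab lineages. Convergent variants
  apply the *same* edit independently in K labs; carrier plasmids are
  built minimal, with per-lab-distinct cassette context, so the K
  lineages share nothing rare and the planted origin count is
  identifiable by construction — the spec of what "independent origins"
  means in the simulation, not an optimisation against any test.
  Edits are single substitutions placed away from part termini (a
  terminal substitution would be trimmed by local alignment and
  masquerade as a terminal deletion); CDS edits are constrained to be
  non-synonymous and stop-free.

### Why convergent variants must live on long parts

A convergent variant is only recognisable as such if the segment carrying
it is counted as *common* corpus content, which requires canonical copies
of the part to match the variant segment at ≥ 98% identity. Segment
boundaries include a few chance-matched flanking bases, each potentially a
mismatch against other plasmids. On a ~70 nt promoter the 2% budget is a
single mismatch — consumed by the planted edit alone — so canonical
copies fall below the bar, the variant segment looks corpus-rare, and
unrelated carrier labs get linked. On CDS-scale parts (≥ 300 nt) the
budget is 6+ mismatches and the edit is absorbed. The generator therefore
plants convergent variants in CDS-scale parts. This is a real boundary
condition of the method, not a simulation artifact: recurrence of
variants of very short parts is intrinsically hard to call with a fixed
98% identity window.

### What the generator does not emulate

Realistic part-frequency distributions beyond the common/rare structure
described; sequencing error; partial or nested part annotations;
rearrangements, transpositions, or multi-edit variant haplotypes; lab
metadata noise (each plasmid has exactly one clean lab label). Passing
tests on these corpora therefore demonstrate correctness of the scoring,
calibration, clustering and bookkeeping — not performance on the noisier
annotation landscape of a real repository.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own validation sizes: calibration contract on a
25-lab, ~250-plasmid corpus with 10,000 sampled cross-lab pairs;
ground-truth recovery on ten 12-lab, ~55-plasmid noiseless corpora with
scaled thresholds (widespread ≥ 5 labs, convergent K ∈ {2, 3, 4});
segment-finder oracle equivalence on 200 random pairs up to 2 kb. All
randomness flows from explicit integer seeds through one scoped RNG
(`withr::with_seed`), and pipeline reruns with the same inputs and seed
are byte-identical, including the CSV reports and the JSON manifest
(which deliberately records no timestamps).

## Known limitations

* Variant detection inherits local alignment's boundary behaviour:
  changes at the extreme ends of a part cannot be distinguished from
  truncated matches, and parts much shorter than the 28 nt word cannot
  anchor segments at all.
* The pairwise clustering step is quadratic in the number of carriers;
  the observation-count gate bounds it exactly as on repository-scale
  corpora, at the cost of never measuring convergence for the most
  common variants (they are caught by the widespread rule instead).
* The E-value is an ungapped Karlin–Altschul stand-in with an
  approximate K; it is documented as non-binding under the package's
  filters rather than as a calibrated significance estimate.
* Lab identity is exact string match after trimming and case-folding;
  no fuzzy matching of depositor names is attempted, so a lab renamed
  between deposits counts as two labs.
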