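---
title: "Methods: copy-number analysis of a gene repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number analysis of a gene repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcnv)
```

This vignette documents the models, parameter choices and numerical
conventions behind `orcnv`, and what the synthetic-data module does and
does not emulate.

## Coordinate and overlap conventions

Positions are 1-based. A span's size is `end - start` bp, i.e. spans behave
as end-exclusive intervals in all size and overlap arithmetic. This is the
only convention under which published breakpoint tables reproduce exactly:
22,317,500–22,588,019 is 270,519 bp and prints as 271 kb under half-up
rounding (`span_kb()`). On-disk BED-like files are 0-based half-open and
converted at the I/O boundary.

Reciprocal overlap of two spans is the intersection length divided by each
span's own size; the validation predicate requires **both** fractions to
reach the threshold (default 0.5). One threshold semantics is used
everywhere — call collation, call-set validation, Jaccard matching, trio
inheritance, cross-population CNP identity — because published pipelines
state a single 50% rule and using one semantics keeps the stages mutually
consistent. Gains and losses are always matched separately (same-type
rule) unless `ignore_type` is set.

## Emission model and segmentation

A probe's log2 ratio under integer copy state $c \in \{0,\dots,4\}$ is
modelled as $\mathcal{N}(\log_2(c/2),\ \sigma^2)$, homoscedastic across
states. $c=0$ has no defined mean; a floor constant of $-2.5$ is used,
reflecting how array intensities saturate rather than diverge for
homozygous deletions (configurable via `or_state_means()`). States above 4
are not modelled: the analyses downstream only distinguish duplication
versus deletion classes, so higher amplifications add nothing testable.

Segmentation is exact Viterbi decoding of a five-state homogeneous HMM.
The self-transition probability defaults to 0.999, an expected run length
of about 1000 probes between state changes; with a 600 bp marker spacing
this prior favors events of at least a few probes and suppresses
single-probe noise, consistent with the conventional ">1 kb and >5 probes"
retention defaults. Ties in the backtrace are broken toward the diploid
state, then toward the lower state index, so decoding is deterministic and
conservative. Call boundaries are the first and last probe positions of
the decoded run (marker-delimited breakpoints), not midpoints between
probes — matching how array studies report start/end markers.

The LOD score of a call is the summed per-probe log10 likelihood ratio of
the called state against state 2. It is additive over independent
segments and linear in segment length for fixed per-probe evidence; the
retention default LOD ≥ 10 is the conventional cutoff quoted as an
approximate 5% false-discovery rate in array CNP calling. That LOD↔FDR
mapping is treated as an assertion from practice, not re-derived here.

The companion threshold caller estimates the null spread robustly (MAD
about the median per sample and chromosome, so planted events do not
inflate it), seeds candidate runs beyond `max(k_sd)` standard deviations
and extends them at `min(k_sd)`, keeping runs of ≥ 5 probes and merging
same-type runs separated by fewer than 2 probes. The per-region genotyper
summarizes each sample by the median log2 ratio over the region's probes
and classifies against the canonical state means (nearest mean; ties go to
the lower state), recording the population mode so the "state differs from
mode" retention rule can be applied.

## Retention, collation and QC

Retention follows the conventional rules: LOD ≥ 10 (inclusive; calls
without a LOD, e.g. genotyper calls, are not LOD-filtered), size strictly
greater than 1 kb, strictly more than 5 probes, non-diploid state, and
genotyper calls only when off the population mode. Cross-algorithm
duplicates — same sample, same type, ≥ 50% reciprocal overlap, different
algorithms — are collated into one record keeping the union span and the
maximum LOD; the merge is transitive (union–find) and idempotent. Jaccard
comparison of two call sets matches greedily by descending overlap,
one-to-one; greedy matching is reproducible and order-independent after
sorting, which is why it was chosen over an unstated optimal matching.
Sample QC gates on call rate > 0.97 and contrast QC > 0.4 (strict
inequalities, so a sample at exactly 0.97 fails) plus a configured
exclusion list standing in for population-structure outlier removal, which
is out of scope here.

## Recurrence classes

Events are nodes of a per-chromosome interval graph; edges join pairs with
minimum reciprocal overlap ≥ 40% (merged regions) or ≥ 99% (families).
Whether the published 40% is reciprocal or one-directional is not stated;
it is implemented as reciprocal (minimum of both fractions) and exposed in
the API. Maximal cliques are enumerated exactly; each event is assigned to
the largest clique containing it, ties broken by leftmost region span then
lexicographic member ids, so the partition is deterministic. Classes:
`rare` = region with events of exactly one individual; `hotspot` = region
with events from at least `hotspot_min_individuals` (default 3)
individuals; `intermediate` otherwise. The hotspot/intermediate boundary
is not published anywhere we could anchor it, so 3 is a package default
chosen as the smallest count that is unambiguously "recurrent across
individuals", and it is a visible parameter rather than a constant.

## Cross-population sharing

Population-level CNPs are connected components of the ≥ 50%
reciprocal-overlap graph over all retained calls (same type). Components,
rather than cliques, are used here because a population-level CNP is an
identity relation ("the same polymorphism seen in several cohorts"), and
transitive closure makes the table invariant to which population
contributed the widest call. Each CNP records its union span, integer-kb
size, the set of carrying populations and exclusivity;
`conserved_breakpoints()` groups CNPs sharing a start or end coordinate
within a tolerance (default 0 bp, exact reuse) to expose the
common-start/alternate-end pattern of breakpoint reuse.

## Trio classification

A child call is `inherited` when a same-type parental call matches at
≥ 50% reciprocal overlap, `de_novo` otherwise, `unknown` when a parent is
missing from the pedigree. The trio rule is deliberately the same overlap
rule as validation; no separate trio threshold is published. Because trio
summaries in the literature are reported under two different
normalizations (within duplication/deletion type, and over all events) and
the two are easy to confuse, `inheritance_summary()` reports **both**,
explicitly labelled, rather than guessing a convention.

## Flank homology and trees

For each breakpoint, the upstream flank covers the 1 kb before the start
point and the downstream flank the 1 kb after the end point, truncated and
flagged at chromosome edges. Screening aligns each flank (exact
Smith–Waterman with affine gaps: match +1, mismatch −1, gap open −2 for
the first gapped column, −1 per extension) against 2 kb windows stepped
1 kb across every chromosome of every panel genome, merging
window-duplicated hits at a locus and keeping the best. Identity is
`100 × matches / alignment columns`, so gaps (and `N`s) count against
identity — the common convention for reported local-alignment identities.
A hit needs ≥ 95% identity **and** at least half the flank aligned; the
coverage requirement exists because a pure identity threshold is
satisfiable by short perfect matches in random sequence, and the published
"percent overlap" threshold conflates identity and coverage — both are
explicit, separately settable parameters here. Hits at the flank's own
locus are labelled `self`; other same-genome loci `paralogous_derived`;
other genomes `orthologous`; the closest non-self hit in identity is
flagged as the nominated recombining region. Repeat/CpG masking is a no-op
by default: the screening operates on synthetic panels without repeat
structure, and the analyses it reproduces found repeats uninformative.

Distances for trees are `100 − %identity` from global alignments. UPGMA is
implemented directly (size-weighted average linkage, merge heights d/2)
with ties broken toward the lexicographically smallest label pair so the
output tree is unique; trees are ultrametric to well below 1e−9 in leaf
depth. Neighbor joining uses the canonical Q-criterion implementation from
\pkg{ape}, with negative branch lengths clamped to zero under a warning;
on additive matrices it reconstructs the generating tree exactly. Both
tree types are emitted for any set of flank sequences; no topology claim
is asserted between the location-based and family-based groupings — the
package computes the trees, the contrast is for the analyst.

## The synthetic-data module

The generator is the package's substitute for raw arrays, and its defaults
encode the study conditions it emulates:

* **Array geometry** — probes every 600 bp (the "median inter-marker
  distance of 500–600 bases" regime) on hg18-style-named synthetic
  chromosomes totalling ~8.6 Mb by default; desk-scale, not genome-scale.
* **Noise** — Gaussian log2-ratio noise, default sd 0.1, a typical
  high-quality array track; accuracy-oriented tests use 0.05.
* **Event palette** — two cohort-wide recurrent duplication analogues
  (271 kb and 318 kb), one 364 kb deletion analogue absent from the first
  population, one exclusive event per population, and two single-carrier
  (rare) events exercising copy states 0 and 4. Carrier draws are
  Bernoulli at the configured per-population frequency, or an exact
  carrier count for rare events. No per-event size distribution is
  published for the real call set; where random de novo events are needed
  the generator draws sizes log-uniformly on 50–500 kb, a modelling choice
  documented here once and not revisited.
* **Annotation** — 862 genes, intact fraction 0.4698 (so exactly 405
  intact genes at the default size; the expected value of the Bernoulli
  draw is fixed for reproducibility), placed non-overlapping inside
  cytoband-labelled clusters that the palette events overlap.
* **Trios** — each child event is an exact parental copy with probability
  `fraction_inherited` (default 0.15, the inherited share reported for
  family cohorts) or a de novo interval disjoint from all parental events.
* **Flank panels** — a self genome plus up to five related-species
  genomes (40 kb chromosomes), with 8 paralogous and 4 orthologous copies
  of a 1 kb flank planted at exact identities in \[0.96, 1.0\] — the hit
  pattern reported for the most common CNV start point — mutated by
  substitution only.

Identical configurations (including the seed) give byte-identical outputs;
every stage's truth is recorded.

**What passing tests do and do not show.** The simulator emulates mean
shifts, Gaussian noise, population structure of carriers and exact planted
truth. It does **not** emulate GC/wave artefacts, probe-specific biases,
allele-intensity (A/B) channels, mosaicism, segmental-duplication
misalignment, or repeat-rich flank structure. Recovery rates measured on
it are therefore upper bounds on real-array performance, and the
population-level percentages of the real studies (carrier rates, event
counts, hotspot tallies) are reproduced as *patterns* on synthetic
designs, not as numbers.

## Numerical choices and degenerate inputs

* Viterbi ties → diploid state; genotyper ties → lower state; UPGMA ties →
  smallest label pair; clique-assignment ties → largest, then leftmost.
* Empty probe track → empty call set; all-identical intensities → the
  threshold caller warns and returns no calls; two empty call sets →
  Jaccard 1 with a warning; a region with no probes, an unsorted track, a
  call covering no probes, non-ACGTN sequence, a non-symmetric distance
  matrix → errors.
* Tests compare clique enumeration with exhaustive subset search on up to
  12 events (the largest size where 2^n enumeration stays instant), and
  alignment scores with exhaustive alignment-path enumeration on pairs up
  to ~6 bp (enumeration is exponential; beyond that an independent
  implementation serves as the cross-check). Viterbi is checked against
  full 5^n path enumeration for tracks up to 7 probes.
* Test problem sizes — 8–60 samples, 1.5–8.6 Mb genomes, 10-seed
  replicates — are chosen so the full suite completes in about a minute
  while every planted feature spans hundreds of probes.

## Known limitations

* The HMM is homoscedastic and single-platform; no B-allele frequencies,
  no mixture normalization, no SNP genotyping.
* Only the HMM segmentation route is implemented; the univariate versus
  multivariate cut-point variants named in console software are not
  specified anywhere reproducible.
* Flank screening is exact but brute-force (no k-mer seeding); it is meant
  for desk-scale panels (≤ ~10 Mb), not genome-scale BLAST replacement.
* The LOD ≥ 10 ↔ ~5% FDR mapping is adopted, not estimated.
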