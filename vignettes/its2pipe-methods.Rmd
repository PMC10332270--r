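---
title: "its2pipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{its2pipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the pipeline does

`its2pipe` implements a complete ITS2 amplicon metabarcoding inference
chain for soil-algae communities targeting four algal classes
(Chlorophyceae, Trebouxiophyceae, Ulvophyceae, Xanthophyceae), together
with a synthetic data generator that produces reads with known ground
truth. The stages are:

1. **Primer screening and pool splitting** — read pairs are assigned to
   one of two amplicon systems ("green" for the three green-algal classes,
   "xantho" for Xanthophyceae) by matching both primers within a mismatch
   tolerance (default 1, no indels); pairs matching with swapped mates are
   re-oriented 5'→3'; everything else is discarded.
2. **Merging** — best ungapped overlap maximizing matching bases, subject
   to a minimum overlap (10 bp) and a maximum overlap mismatch fraction
   (0.1). At overlap mismatches the higher-quality base wins and keeps its
   quality; at matches the higher quality is kept. This replaces a
   statistical merge test with a deterministic, desk-scale rule that is
   exactly reproducible by an exhaustive offset scan.
3. **Quality filtering** — keep a merged read iff length > 200 bp and the
   expected number of errors, $\sum_i 10^{-Q_i/10}$, is < 1 (both strict).
4. **Dereplication** — exact-string grouping with per-sample counts,
   sorted by decreasing abundance (ties lexicographic).
5. **De novo chimera flagging** — a candidate is chimeric when a single
   crossover between two parents (each at least 2× more abundant, top 20
   considered) explains it better than any single parent by at least 0.02
   identity *and* the crossover model itself matches the candidate at
   ≥ 0.99 identity (see "Chimera specificity" below).
6. **ITS2 trimming** — the core between two conserved 20-mer flank motifs
   (5.8S / 28S proxies), each matched within 1 substitution. This is a
   motif-proxy stand-in for HMM-based ITS2 extraction: exact on synthetic
   data, *not* equivalent on real-world sequences.
7. **Greedy centroid clustering at 97%** — abundance-sorted, every
   sequence compared against all existing centroids (the equivalent of
   `maxaccepts = maxrejects = 0`), joining the best centroid at ≥ 0.97
   identity or founding a new OTU. Amplicon pools are pooled after
   trimming and clustered together.
8. **Abundance floor** — OTUs below 0.005% of the initial read count of
   their amplicon group are removed (logged, not reassigned).
9. **Clone co-clustering** — long clone-library sequences (ITS2-trimmed)
   are assigned to their best centroid at ≥ 0.97; such OTUs become
   "mixed". Unassigned clones form clone-only clusters. Clones carry no
   read abundance.
10. **Taxonomy by normalized bit score** — see below.
11. **Overlap classification and community statistics** — Venn-style
    presence across the multi-site group A (with its northern/southern
    sub-parts) and the single-site reference group B; per-class OTU
    composition; Observed/Shannon/InvSimpson; rarefaction; Kruskal–Wallis;
    per-genus NB box statistics; top-20-per-class abundance matrices.

## The NB statistic and consensus taxonomy

Each OTU centroid is searched against the reference set with a local
aligner using blastn default scoring (match +2, mismatch −3, gap open 5,
gap extend 2). Raw scores $S$ become bit scores
$S' = (\lambda S - \ln K)/\ln 2$ with the gapped Karlin–Altschul
parameters $\lambda = 0.625$, $K = 0.41$, and E values
$E = m\,n\,2^{-S'}$. The **normalized bit score** is

$$NB = S' / \text{subject length}.$$

For a full-length perfect match, $NB = (2 \lambda L - \ln K)/(L \ln 2)
\approx 1.81$ for $L$ near 228 bp — the NB ceiling. Identity classes:

* **genotype**: $NB \ge 1.81 - 0.005$ (entire sequence identity; the
  tolerance absorbs the small length dependence of the $-\ln K$ term),
* **species**: $1.75 \le NB <$ ceiling,
* **unidentified**: below 1.75.

Consensus assignment per OTU works on the 50 recorded hits:

1. *Non-target suppression*: if the summed bit score of target-class hits
   exceeds the non-target sum (evaluated over all 50 hits), non-target
   labels (e.g. "uncultured fungus") are excluded from candidacy;
   otherwise the OTU is called non-algal.
2. *Rank ladder*: over the top 10 remaining hits, the label with the
   highest bit-score sum is the candidate at each rank, from genotype
   upward. The most specific rank whose candidate is supported by a best
   hit reaching the relevant NB band is assigned (genotype requires the
   ceiling, species requires ≥ 1.75); failing both, the call falls back to
   "\<genus\> sp.", then "unidentified \<order\>", then
   "unidentified \<class\>". Ties break by best single bit score, then
   lexicographically.

Because hit tables are plain 15-column BLAST-style TSVs, a precomputed
table can be substituted for the built-in aligner
(`run_pipeline(..., hit_table = )`), which the tests use to verify that a
taxonomy-only rerun reproduces the full run.

**Subject length choice.** References enter the search as ITS2 cores, so
the NB denominator is the trimmed reference length. Had the conserved
flanks been kept in the subjects, a perfect core match would cap NB near
$1.80\,L/(L+40) \approx 1.55$, making the genotype and species bands
unreachable — inconsistent with the ceiling being attained at full
identity. Clone sequences are likewise ITS2-trimmed before co-clustering.

## The synthetic world

The generator's defaults are the stated conditions of the analysis, chosen
once:

* **Taxonomy**: 4 classes × 3 genera × 2 species × 2 genotypes (48
  genotypes), 2 order-rank labels per class.
* **Divergence bands** (pairwise, on ITS2 cores): genotypes within a
  species ≤ 0.02, species within a genus 0.04–0.15, genera within a class
  0.15–0.40; classes are unrelated random roots. Sequences evolve by
  i.i.d. substitutions from per-class roots with mutated position sets
  kept disjoint along lineages and between siblings, so realised pairwise
  divergences are sums of branch fractions and land inside the bands
  (verified exhaustively in the tests, ± 0.02). Each genotype after the
  first in a species receives at least one private substitution so that
  genotype names map 1:1 to sequences.
* **Core lengths**: per-genus, normal(228, 25) clamped to 174–295 bp —
  the length range and average of the real ITS2 amplicons.
* **Mislabeled references**: 10% of genotypes gain an *extra duplicate*
  record labeled "uncultured fungus clone" (lineage hidden). They are
  duplicates rather than replacements so that every genotype keeps one
  correctly labeled reference — as in public databases, where mislabeled
  and correct entries coexist. This is what exercises the non-target
  suppression rule.
* **Communities**: group A holds 65% of genotypes, group B 45%, and the
  fraction of group-B genotypes shared with group A is the
  `shared_fraction` (default 0.35) up to rounding. Abundances are
  log-normal (σ = 1) per group with mild per-site jitter (σ = 0.3);
  7 group-A sites (4 north, 3 south) and 1 reference site at 50,000
  expected reads each — read depth per site is a free choice documented
  here, since only totals are known for the real study.
* **Reads**: 200 bp including a 20-bp primer tag; constant Phred quality
  $Q = -10\log_{10}(e)$ (capped at 40) so expected-error filtering is
  analytically predictable; default per-base substitution rate 0.001
  (below the 1/335 maxEE cliff, as for real post-merge data the filter is
  meant to pass); chimera rate 0.01 (two-parent single crossovers at a
  uniform breakpoint within the same amplicon system); off-target
  fraction 0.02, emitted under a third, non-matching primer pair so that
  screening removes it.

**What a green test does not establish.** The generator has no indels, no
quality degradation along reads, no PCR bias, no length variation within a
genus, and its flank motifs are exact proxies — so passing tests validate
the inference chain's logic, not ITSx-equivalence or robustness to
real-world artifacts.

## Numerical and design choices

* **Clustering identity** is matching columns / alignment span in an
  ends-free global alignment, where *terminal gap columns count in the
  span* (vsearch's iddef-0 flavour). With terminal gaps excluded, an
  accidental 10-bp perfect dovetail between unrelated sequences scores
  identity 1.0 and the clustering collapses; counting the span restores
  the intended behaviour while leaving equal-length comparisons (the only
  ones inside the bands) untouched. Equally similar centroids resolve to
  the earlier-founded, more abundant one.
* **Chimera specificity.** The improvement-only crossover rule
  (model − best single ≥ 0.02) false-flags ~10% of genuine sequences in
  this world: disjoint-position evolution makes two relatives'
  substitution sets separable by a breakpoint surprisingly often. A true
  PCR chimera, however, *is* its crossover model up to sequencing error,
  so the implementation additionally requires the model to match the
  candidate at ≥ 0.99 identity. With it, the false-positive rate on
  chimera-free data is 0 in the test suite and constructed chimeras are
  still flagged.
* **OTUs resolve species, not genotypes.** Sibling genotypes are ≤ 2%
  divergent by construction, hence ≥ 98% identical, and co-cluster at the
  97% threshold — necessarily. The parameter-recovery tests therefore
  assert a bijection between OTUs and *species-level* clusters present in
  the truth, plus genotype-level correctness of each centroid's taxonomy
  call (the centroid is the most abundant genotype's exact sequence, and
  its call must name that genotype). This mirrors the field convention in
  which an OTU is a species-like unit and "genotype identity" is a
  property of its representative's best reference match (NB at the
  ceiling).
* **Quartiles** in the NB box statistics use linear interpolation
  (`stats::quantile` type 7, the ggplot2 convention); whiskers extend to
  the most extreme values within 1.5 IQR of the quartiles.
* **Shannon** uses the natural logarithm; inverse Simpson is
  $1/\sum p_i^2$; empty samples report missing values.
* **Abundance floor denominator**: the floor (0.005%) is applied per
  amplicon group against that group's post-screen read count; the raw
  pre-screen total is not attributable to a group because off-target
  reads belong to none.
* **Percentages** are rounded to 1 decimal only at the presentation layer
  (`headline_percentages()`); internal values stay unrounded.
* **Determinism**: one master seed; per-stage seeds derive from it by a
  stable arithmetic hash of the stage name, so stage-skipping reruns stay
  reproducible. Rerunning with the same config yields byte-identical
  written artifacts (md5-checked in the tests).

## Known limitations

* The aligner records one best local alignment per query–subject pair (no
  multiple HSPs) and uses fixed Karlin–Altschul parameters rather than
  length-adjusted ones; E values are therefore approximate. NB, the
  quantity that matters downstream, does not depend on the E value.
* The merger's quality model keeps the max quality at agreeing overlap
  bases rather than a posterior combination.
* Chimera detection flags only; breakpoints near read ends and crossovers
  between near-identical parents are undetectable in principle (their
  models do not beat the best single parent by the margin).
* The motif-proxy ITS2 trimmer requires the conserved flanks the
  generator embeds; on real data an HMM-based extractor must replace it.
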