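---
title: "Methods: DNase I hotspot detection, temporal clustering and conservation analysis"
author: "dhsatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNase I hotspot detection, temporal clustering and conservation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhsatlas)
library(GenomicRanges)
```

# The detection model

DNase I preferentially cleaves nucleosome-depleted chromatin, so
regulatory elements appear as local pile-ups of sequenced cleavage tags.
`dhsatlas` scans each chromosome with 150-bp windows stepped every
20 bp. A window containing `c` of the `n` tags found in a 50-kb local
background centred on it is scored with the binomial upper tail

$$p = P(X \ge c), \qquad X \sim \mathrm{Bin}\!\left(n, \tfrac{150}{50\,000}\right).$$

The local background absorbs megabase-scale variation in tag density
(mappability, copy number, broad chromatin domains): only enrichment
relative to the surrounding 50 kb is called. The binomial model assumes
tags fall independently and uniformly within the background when no
regulatory element is present — the same assumption under which the
null datasets for FDR calibration are generated, which keeps the
calibration internally consistent. Near chromosome ends the background
is clipped and the success probability uses the clipped length, so edge
windows are scored against their actual background.

Windows at or below the threshold merge into **hotspots** when they
overlap or abut within one step (20 bp); overlapping windows share
signal by construction, so adjacency implies a continuous enriched
region. Within each hotspot, window-count local maxima are ranked and
150-bp **peaks** are emitted greedily, skipping maxima whose peak would
overlap one already emitted; plateaus contribute their centre window,
and summits within 75 bp of a chromosome end are shifted inward. Every
hotspot yields at least one peak.

Before scanning, samples sequenced to different depths are made
comparable by random down-sampling without replacement (the
conventional full-scale target is 25 million tags; it is a parameter,
not a code path).

## FDR calibration and SPOT

The detection threshold is not fixed a priori. Uniform random tag sets
at the sample's exact depth are scanned with the identical
count/p-value/merge chain, and the FDR at a threshold is estimated as
(mean simulated hotspot count)/(observed hotspot count). A bisection
over $-\log_{10} p \in [2, 12]$ (25 iterations) selects the most
permissive threshold whose estimate stays below the 1% target. Window
p-values for the observed sample and each null replicate are computed
once and reused across iterations, so calibration costs little more
than the null scans themselves. When no observed hotspot is found the
estimate is degenerate and reported as 1 with a warning.

The **SPOT score** — the fraction of tags inside hotspots — is recorded
per sample as a library-quality metric and reused later as a
normalization divisor.

# Temporal clustering

For the master list (the sorted, non-redundant union of all samples'
peaks, merged transitively), each sample contributes the maximum
tags-per-million window density over each master DHS. The matrix is
then normalized in exactly this order:

1. divide each sample's column by that sample's SPOT score (corrects
   signal-to-noise differences between libraries),
2. transform by $\log_{10}(\text{density} + 1)$ (compresses the heavy
   right tail),
3. scale each row so its maximum is exactly 10 (profiles become
   shapes; all-zero rows stay zero).

The row scaling is computed as `(v / max) * 10`, which makes the row
maximum exactly 10 in floating point rather than within rounding.

k-means (Euclidean distance, Lloyd iterations, best of 25 random
starts, 300 iteration cap, k = 12 by default) partitions the rows into
temporal groups. Should Lloyd abort on an empty cluster, the fit falls
back to Hartigan–Wong under the same seed; both paths are deterministic
given the seed. Centroids are labelled: **C** (constitutive) when
$(\max - \min)/\max \le 0.2$; otherwise **O** (other) when the profile
has an interior minimum below both ends (a valley — activity that
disappears and returns); otherwise **E**/**M**/**L** by the stage of
the maximum. The 0.2 flatness tolerance and the valley rule are package
choices — published cluster labels of this kind are shown, not defined
— and both are configurable. All-zero rows are clustered with
everything else (they land in a low/constitutive group) so the matrix
and master list stay aligned.

# Annotation and enrichment

* **Promoter**: a DHS intersecting the strand-aware 1-kb region
  upstream of any TSS. The boundary is closed at exactly −1000.
* **Genomic partition** precedence: promoter ≻ exon ≻ intron ≻
  intergenic, the latter split at 2.5 kb from the nearest TSS into
  proximal/distal (the published category plots do not state the
  boundary; 2.5 kb is the package default, configurable).
* **Occupancy**: a ChIP peak overlapping exactly one DHS by ≥ 75 bp
  marks it occupied; peaks reaching two or more DHSs at ≥ 75 bp each
  are ambiguous, excluded, and counted; remaining peaks count as
  non-overlapping.
* **Specificity**: a target DHS is region-specific when its overlap
  with every single DHS of every comparison set stays below 25 bp (the
  only cross-set mapping threshold stated for such comparisons; the
  per-pair maximum, not the summed overlap, is thresholded).
* **Motif enrichment**: a DHS carries a TF's motif when any linked hit
  with match p-value < 1e-4 overlaps it by ≥ 1 bp; multiple motif
  models per TF pool by union. Cluster-versus-universe enrichment uses
  the exact hypergeometric upper tail (inclusive of the observed
  count, via `phyper`), with one Bonferroni family over the full
  TF × cluster grid and significance at corrected p < 0.01. The match
  threshold is written `10e-4` in some motif-scanner conventions; it
  is interpreted here as the scanner default 1e-4 and is configurable.

# Conservation

Through an orthology interval map, a DHS is **unalignable** (no
record), **shared** (mapped target interval overlaps a partner-species
DHS by ≥ 25 bp) or **diverged** (mapped, no partner DHS). Split
mappings collapse to the largest aligned block. Region distributions
over the three categories are compared pairwise by Pearson chi-squared
on the 2 × 3 count table without continuity correction (df = 2; counts
in this setting are large, and low expected counts surface the usual
approximation warning rather than an error).

# The synthetic study

The generator defines the study conditions under which the pipeline is
exercised and validated:

* genome of 2 chromosomes × 5 Mb; 2,000 planted, pairwise
  non-overlapping 300-bp DHSs separated by ≥ 1 kb,
* three ordered stages (P0, P7, Adult); each DHS follows one of four
  archetypes with stage weights E = (1, 0.4, 0.15),
  M = (0.3, 1, 0.3), L = (0.15, 0.4, 1), C = (1, 1, 1), drawn with
  equal probability by default,
* 1 million tags per sample: uniform background plus in-DHS rates of
  10 × (archetype weight) relative to background per bp,
* ChIP peak sets with a controlled fraction overlapping a planted DHS
  by ≥ 75 bp (round-half-to-even of fraction × count, so the planted
  counts are deterministic), the rest placed clear of all DHSs,
* motif hit tables with per-DHS presence probability `backgroundRate`
  outside a TF's target archetype and `min(1, backgroundRate × odds)`
  inside it, every hit below the scan threshold,
* orthology maps with exact shared/diverged/unalignable counts by
  largest-remainder apportionment.

The archetype weights and the 300-bp width/10-fold enrichment are
package choices of a realistic desk-scale regime (weights follow the
qualitative early/mid/late/flat shapes such atlases report; exact
published effect sizes and background cleavage rates are not stated
anywhere usable). The generator is deliberately idealised: background
cleavage is uniform (no sequence bias or mappability structure), DHS
boundaries are sharp, stages are independent samples, and no replicate
structure exists. Passing tests therefore demonstrate correctness of
the algorithms under their own model assumptions — recovery of planted
truth, calibration of the null — not performance on real DNase-seq
libraries, where sequence bias, copy-number variation and chromatin
domain structure violate uniformity.

## Scales used by the shipped checks

The test suite runs the full calibration benchmark at the default
demonstration scale (2 × 5 Mb, 2,000 DHSs, 1 M tags, 20 null
replicates) and the remaining checks at reduced sizes chosen so each
isolates one property: clustering recovery at 5,000 × 3 with noise
σ = 0.5 over 10 seeds; enrichment null calibration over 1,200
TF × cluster tests; occupancy against a brute-force all-pairs oracle at
a few thousand intervals; conservation type-I control over 200
replicate pairs at n = 5,000. The end-to-end pipeline test uses a
1 × 1 Mb genome with 200 DHSs, which is the smallest study on which 12
clusters, occupancy and conservation are all non-trivial.

# Numerical choices and degenerate inputs

* Binomial and hypergeometric tails use R's `pbinom`/`phyper` (exact to
  double precision in the regimes used; the test suite verifies the
  hypergeometric tail against full enumeration for every instance with
  a universe of 30 or fewer and the binomial tail against explicit
  log-space summation to relative error 1e-3).
* Zero window count gives p = 1; a motif with zero background
  prevalence is flagged degenerate with p = 1; an empty comparison set
  returns the target unchanged with a warning; empty DHS sets are
  excluded from overlap clustering with a warning.
* Internal coordinates are 1-based closed (`GRanges`); BED and
  orthology-map files are converted at the I/O boundary, FIMO-style
  tables are already 1-based inclusive.
* All randomness flows through explicit integer seeds; identical
  configuration and seed reproduce byte-identical reports
  (`runAll()` embeds an MD5 hash of its configuration in every table
  it writes).

# Known limitations

* The hotspot scorer follows the binomial-tail description of the
  published method; it is not a byte-compatible clone of the original
  two-pass implementation, whose exact z-score refinement is specified
  only in external project documentation.
* One sample per stage: no replicate merging or irreproducibility
  filtering.
* The k-means labelling rule (flatness 0.2, valley ⇒ other) is a
  reconstruction; with real data the O clusters may warrant post-hoc
  inspection.
* Peak-calling translation invariance holds for shifts that are
  multiples of the window step; sub-step shifts can move windows across
  grid boundaries by construction.
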