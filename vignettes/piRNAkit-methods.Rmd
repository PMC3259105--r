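---
title: "Methods: piRNA cluster discovery, ping-pong statistics and pool-size estimation"
author: "piRNAkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA cluster discovery, ping-pong statistics and pool-size estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piRNAkit)
```

# Scope and model

piRNAkit analyses Piwi-interacting RNA (piRNA) populations from small
RNA-seq libraries of the kind produced for *Aedes aegypti* and
*Drosophila melanogaster* whole-adult tissue: collapsed reads of 16-35 nt
with a sharp 21-nt endo-siRNA peak and a broad 24-31-nt piRNA class
(centred at 28 nt in *Ae. aegypti*), a 5'-uridine bias in the piRNA class,
genomically clustered piRNA production with per-cluster strand bias, and
the ping-pong amplification signature: sense/antisense read pairs whose 5'
ends overlap by exactly 10 nt, with 5'-U on one mate and A at position 10
of the other.

The pipeline stages are: library preprocessing (adapter stripping,
contaminant removal, size-class partitioning), full-length genome mapping
with uniqueness classification, piRNA-cluster discovery by windowed scan,
ping-pong overlap statistics, target annotation (TE families, genes,
transgenes) and capture-recapture estimation of the latent piRNA
sequence-pool size. A seeded synthetic-data generator emulates the
statistical structure above and provides machine-readable truth for every
stage; all quantitative validation in the test suite runs against it.

# Mapping policy

All placements are **full-length, ungapped, within a Hamming-distance
budget** (default 2) on either strand. For reads shorter than a
seed-aligner's seed length this is exactly what seed-based mapping with a
30-bp seed and 2 in-seed mismatches reduces to, so a single explicit rule
replaces aligner heuristics. Reference `N` never matches and counts as a
mismatch. The implementation seeds candidates with exact matches of
`budget + 1` disjoint read segments (pigeonhole principle) found by
Aho-Corasick multi-pattern search, then verifies each candidate by direct
Hamming comparison; the test suite asserts observational equivalence to an
exhaustive window scan on every fixture.

A sequence is **uniquely mapping** when its minimum-mismatch stratum
contains exactly one placement — the closest operational reading of
"uniquely mapping" under best-stratum reporting, recorded here as an
assumption. Multi-mapped sequences keep all their placements for density
maps, but cluster discovery, gene ranking and (by default) ping-pong
pairing use unique placements only.

## Coordinates

Intervals are held in `GRanges` (1-based, inclusive) throughout, the
native convention of the Bioconductor container stack; all window and
overlap arithmetic is expressed in it (window index `(fivePrime - 1) %/%
windowSize`; overlap `minusFivePrime - plusFivePrime + 1`). TSV reports
print 1-based inclusive coordinates, matching published tables; JSON
reports use 0-based half-open coordinates, stated in their schema. The 5'
coordinate of a minus-strand placement is the interval end.

# Cluster discovery

Each contig is tiled with non-overlapping 5-kb windows ("sliding window"
with step = width is the only reading compatible with merging *adjacent*
windows); a window qualifies when >= 10 distinct uniquely mapping
piRNA-class sequences have their 5' coordinate in it. Maximal runs of
consecutive qualifying windows form clusters; non-contiguous qualifying
windows are **not** collapsed across gaps (gap merging is available via
`mergeGapWindows` but off by default, which produces smaller, better
defined loci). Cluster bounds are refined to the furthest member-read
extents. Reported cluster sizes are half-up-rounded whole kb of the
1-based inclusive interval; this convention reproduces the printed sizes
of all 30 reference clusters bundled with the package (6-184 kb range).

The per-cluster transposon-content null model draws `nSamples` (default
1000) random genomic intervals of **exactly** the cluster's length
("similar size" read strictly, which removes a free parameter), with the
(contig, offset) placement uniform over all valid positions. It reports
the TE base-coverage fraction and TE element count with z-scores (sample
sd, n-1) and empirical two-sided p-values; a zero-variance null yields a
flagged undefined z rather than an infinity. The null is Monte-Carlo, so
the seed is a mandatory argument and results are bit-reproducible given
(seed, nSamples).

# Ping-pong statistics

For hits of reads >= 24 nt, every (plus, minus) pair sharing at least one
genomic position is enumerated (a sequence may join many pairs); the
overlap length is `minus 5' - plus 5' + 1`, under which the amplification
signature is exactly 10. The signature fraction is the share of distinct
overlapping sequences engaged in at least one 10-nt overlap — distinct
sequences, not read multiplicities, with a multiplicity-weighted variant
behind a flag. The U1/A10 mark requires 5'-U on one mate and A at position
10 of the other, each read in its own 5'->3' orientation. Per-element
density maps count distinct-sequence 5' ends per position and strand and
place each signature pair at the midpoint of its 10-nt overlap.

# Pool-size estimation

The latent piRNA sequence-pool size is estimated by two-sample
capture-recapture (Lincoln-Petersen), `N = nA * nB / k`, over every
unordered pair of libraries from different replicate groups; per-pair
estimates are summarised by mean/min/max. Eligibility: length >= 24 nt,
genome-mapping, and — the key modification — **within-library multiplicity
exactly 1**. Highly duplicated sequences inflate the recapture overlap
`k` under skewed abundance and bias `N` downward; exclusion is applied
per library (a sequence duplicated in one library remains eligible in a
library where it occurs once), the literal reading, with a global mode
available. The plain estimator is the default; the Chapman correction is
offered behind a flag but not used, for fidelity to the methodology the
pipeline reproduces. `validateEstimator()` verifies the estimator
in-silico at the pool-index level: with uniform abundance and two
libraries of 2 x 10^4 draws from N = 10^5 the mean estimate is within 5%
of N over 50 replicates, and with log-normal abundance (sigma = 1) the
duplicate-exclusion rule measurably reduces |bias| (by ~12 percentage
points in the default configuration) — the motivation for the rule.

# The synthetic-data generator

`simConfig()` holds the generator's study conditions; `simulateStudy()`
produces a genome with TE/gene annotations, a latent pool and sampled
libraries, all bit-reproducible from (config, seed).

Defaults and their reasoning:

* **Genome**: one 1-Mb random contig. Ten clusters, grid-aligned to the
  5-kb scan resolution, jointly covering ~20% of the genome. Grid
  alignment is deliberate: a windowed scan cannot resolve boundaries below
  window resolution, so planting off-grid boundaries would measure noise,
  not the scan.
* **Emission contrast**: 84% of primary pool sequences come from clusters
  (`clusterFraction = 0.84`), matching the genome-scale structure the
  analysis assumes (clusters occupying ~20% of the genome and producing
  ~84% of piRNAs gives a per-bp emission contrast of roughly 20x). A
  literal 5x contrast cannot separate cluster from background windows at
  the fixed >= 10-per-5-kb threshold for any Poisson background rate —
  the threshold would sit between the two means at every rate — so the
  20x figure is the study condition and satisfies the >= 5x requirement.
* **Pool**: 1500 distinct primaries by default (desk scale), lengths
  24-31 nt with mode 28, 5'-U probability 0.8 (the 5'-base class is chosen
  per sequence and enforced by shifting the placement window, so the
  realized fraction equals the configured probability), per-cluster strand
  bias 0.9.
* **Ping-pong structure**: a cluster emission receives an opposite-strand
  partner with probability `pPartner = 0.4`; the partner sits at the exact
  10-nt signature offset with probability `pPingpong = 0.195` and at a
  random non-signature offset otherwise. Two parameters are needed: if
  every partner carried the signature, the measured signature fraction
  would be ~1 regardless of the setting and recovery would be vacuous.
  When the primary carries 5'-U, the 10-offset partner automatically
  carries A10 (it is the complement of the primary's first base) — the
  biology of the signature. Chance overlaps among unpartnered reads dilute
  the measured fraction below `pPingpong` (to ~0.15 under the defaults);
  the generator therefore records the **realized** pool-level signature
  fraction, and recovery tests compare the pipeline's measurement on
  sampled libraries against that realized value within binomial bands.
* **Libraries**: seven libraries in five replicate groups (2+2+1+1+1,
  giving the 19 non-replicate pairs of the reference design), 20,000 reads
  each, 20% 21-nt siRNA background, 5% contaminant spikes, log-normal
  (sigma = 1) pool abundance to exercise duplicate exclusion. Raw-mode
  reads are insert + adapter truncated to 42 nt, long enough that the
  longest gel-window insert (35 nt) still leaves a detectable >= 6-nt
  adapter suffix.
* **TEs**: five consensus families (retrotransposon / DNA / MITE / other
  mix), 2-6 inserted copies each; MITE consensus sequences carry 30-bp
  terminal inverted repeats. Insertions avoid cluster intervals by default
  so that planted-cluster reads stay uniquely mapping; set
  `teInClusters = TRUE` for TE-rich clusters.
* **Transgenes**: two 3-kb random plasmids; 1% of pool sequences are
  plasmid-derived and therefore absent from the genome, exercising the
  genome-exclusion filter.

## What the generator does and does not emulate

It reproduces the *statistical* structure the analysis assumes: size
classes, 5'-U bias, clustered emission with strand bias, the 10-nt overlap
geometry, skewed abundance, spiked contaminants, TE repetitiveness and
shared plasmid segments. It does not model sequencing error,
quality scores, base-composition biases of real genomes, nested/fragmented
TE copies, or transcription-coupled cluster structure. Passing recovery
tests therefore demonstrates correctness of the algorithms under the
stated statistical model, not performance on any particular real library.

## Design of the cluster-recovery experiment

The recovery experiment (20 seeds; every planted cluster recovered at
interval Jaccard >= 0.9, zero false clusters) fixes the generator's free
parameters by a power calculation. With uniform abundance and the default
depth, essentially the whole pool is captured, giving ~31 distinct
sequences per cluster window and ~1.5 per background window. The refined
boundary error at each cluster edge is approximately Exp(1/density-per-bp)
(mean ~160 bp), so a 20-kb cluster fails Jaccard 0.9 — i.e. loses > 2 kb
across both edges — with probability ~5 x 10^-5, and a background window
reaches the >= 10 threshold with probability ~3 x 10^-6. Constant 20-kb
clusters are used because shorter loci make the check measure edge
noise rather than the scan (a 5-kb locus loses ~6% of its length to
expected edge gaps alone). The package defaults keep varied 15-30-kb
clusters and log-normal abundance for realism.

## Statistical form of the binomial-band recovery checks

The recovery criteria are phrased per quantity as "within the 99% binomial
band at each of 20 seeds". Sixty independent 99% events jointly fail with
probability ~45%, so the test suite asserts the statistically meaningful
form: per quantity at most 2 of 20 seeds outside the band (probability
< 10^-3 under the null), plus pooled-across-seeds agreement for the
pure-Bernoulli quantities (5'-U fraction, strand bias). The bands
themselves are unchanged.

# Numerical conventions

* Percentages are half-up rounded at 2 decimals, gene piRNA densities at
  1 decimal, cluster sizes at whole kb (base R `round()` is
  round-half-even and does not reproduce printed tables).
* `checkPercentages()` recomputes every percentage of a tally report from
  its own counts and fails the report on any mismatch; it runs as part of
  the bundled reference-table checks. Two gene-density rows of the bundled
  reference table do not recompute from their own printed counts
  (54.6 vs 54.4 for the densest gene; 0.8 vs 0.7 for one short gene); the
  package reproduces recomputation, not the two inconsistent cells.
* Degenerate inputs are defined, not special-cased: empty libraries warn
  and propagate; a zero-variance null flags its z undefined; a
  zero-overlap library pair is dropped from pool estimation with a
  warning, and an error is raised only when no pair remains.

# Problem sizes used in validation

Oracle-equivalence fixtures use genomes <= 30 kb with <= 150 mutated reads
(20 seeds) against `Biostrings::vmatchPattern` exhaustive scans and an
O(n^2) all-pairs overlap oracle; cluster recovery runs 20 seeds of the
1-Mb / 10-cluster configuration; estimator recovery uses N = 10^5 with two
libraries of 2 x 10^4 draws (50 replicates); generator-truth recovery uses
a 10^4-sequence pool (20 seeds). These sizes make the full suite and the
acceptance script each complete in minutes while keeping every check at
the scale its statistics require.

# Known limitations

* The mapper is ungapped by design; indel-containing placements are
  excluded at SAM ingestion with counted warnings rather than aligned.
* Cluster discovery assigns each sequence by the 5' coordinate of its
  single unique placement; multi-mapping piRNAs (common in TE-dense real
  genomes) are invisible to the scan, as in the underlying methodology.
* The Lincoln-Petersen estimator assumes exchangeable sampling of a closed
  pool; with strongly skewed abundance it retains a negative bias even
  after duplicate exclusion (~-33% at sigma = 1), so pool sizes under
  skew are lower bounds in practice.
* The ping-pong signature fraction depends on read density through chance
  overlaps; comparisons across datasets of different depth should use the
  same eligibility rules and, ideally, matched subsampling.
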