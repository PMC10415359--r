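---
title: "Linking clustered G-quadruplex motifs to replication origins: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking clustered G-quadruplex motifs to replication origins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

g4origin implements a genome-scale analysis of the hypothesis that
*clustered* potential G-quadruplex motifs (pG4s) — two to six same-strand
pG4s separated by short gaps — act as a cis-determinant of DNA replication
origins, while isolated (monomeric) pG4s do not. The pipeline has five
statistical components:

1. **pG4 detection and clustering.** The canonical pattern
   `G{3,}(N{1,7}G{3,}){3}` is matched on both strands (the minus strand is
   scanned on the reverse complement, so minus-strand motifs appear C-rich
   on the reference). Same-strand motifs are chained transitively when
   consecutive gaps are at most 100 bp; runs of 2–6 are *clustered*, runs
   of 1 are *monomeric*, longer runs are reported separately as *oversize*.
2. **Matched random background.** Each feature is paired with random
   genomic segments of identical length whose GC fraction falls in the same
   GC bin (2% bins by default), drawn by rejection sampling of uniform
   positions. This is the null model for all enrichment statistics.
3. **Logistic enrichment.** For a feature class, segments (real and
   random) are extended 1 kb around their anchor point and flagged for
   overlap; the log-odds ratio of the flag between the real and random
   class is estimated by a binomial GLM (`class ~ flag`). With one binary
   covariate the estimate equals the closed form `ln(ad/bc)` of the 2x2
   table, with standard error `sqrt(1/a + 1/b + 1/c + 1/d)` and a two-sided
   Wald test. `logOR = 0` means equal association in both classes. A
   strand-aware variant flags an origin when a plus-strand pG4 lies in the
   1-kb window upstream of the origin peak or a minus-strand pG4 in the
   window downstream.
4. **Coverage profiles and origin strength.** Meta-profiles count signal
   features in 20-bp windows stepped by 10 bp over ±1 kb around anchors
   (199 offsets), mirrored for minus-strand anchors. Origin strength is
   SNS reads per bp of origin; *strong* origins are the top 25% by
   strength; strength is stratified by CGI status and by the number of
   monomeric and clustered pG4s within the extended origin span, with
   Student-t 95% confidence intervals per group.
5. **Replication timing.** Reads from four S-phase fractions (S1 early …
   S4 late) are counted in 50-kb windows at 10-kb intervals (read
   midpoint assignment), normalized per window by the asynchronous
   sample's relative coverage, centred and scaled to unit variance, and
   smoothed per chromosome with a cubic smoothing spline
   (`stats::smooth.spline`). The single-track summary is the weighted
   average `WA = 0.750 S1 + 0.583 S2 + 0.417 S3 + 0.250 S4`; higher WA
   means earlier timing. For a locus, the shift between two conditions is
   `RT shift = -ΔL + ΔE` with `ΔL = (%S3+%S4)_with − (%S3+%S4)_without`
   and `ΔE = %S1_with − %S1_without` (percentage points; positive =
   earlier).

# Coordinate and interval conventions

All intervals are 0-based half-open (BED convention), carried in tibbles
with columns `chrom`, `start`, `end`, `name`, `score`, `strand`. Overlap
machinery is delegated to IRanges behind this surface; sequences and FASTA
I/O use Biostrings. Sorting is deterministic (chromosome lexical, start,
end, strand).

Several conventions required a decision where common usage is ambiguous:

* **Anchor point.** Peak coordinates are not distributed with most BED
  files, so the anchor of a segment defaults to the integer midpoint
  `floor((start+end)/2)`; motif-anchored profiles default to the 5' end on
  the motif's strand (`anchor_mode = "first"`), matching how nucleosome
  profiles around pG4s are conventionally drawn. Both are switchable.
* **1-kb extension.** "Extended by 1 kb" is implemented as ±1 kb around
  the anchor point (a 2-kb segment), with the flank exposed as a
  parameter, rather than growing the whole segment by 1 kb per side.
* **Gap rule.** Merging and clustering use `gap <= max_gap` (the semantics
  of distance-`d` interval merging tools), with `strict = TRUE` available
  for a strict `<` reading. The default gap is 100 bp.
* **Oversize runs.** Runs of more than six same-strand pG4s belong to
  neither category; they are reported so users can reassign them.
* **N bases** are excluded from the GC denominator; all-N intervals have
  undefined GC and are excluded from matching (reported as unmatched).
* **Zero cells** in an enrichment table trigger the Haldane–Anscombe
  +0.5 correction on all four cells, flagged in the result, instead of
  dropping the comparison.
* **Percent vectors** passed to the RT-shift statistic must sum to 100
  (tolerance 1e-6); they are never renormalized silently.
* **Standardize, then smooth.** Fraction tracks are centred/scaled before
  spline smoothing, and WA combines the smoothed tracks by default (a
  switch uses the raw standardized tracks). The spline's smoothing
  parameter defaults to generalized cross-validation per chromosome and
  can be fixed via `spar`.
* **Enrichment is univariate** per feature class (one GLM per class),
  matching the closed-form equivalence; p-values are reported raw with an
  optional Benjamini–Hochberg switch.

# The synthetic-data generator

Real inputs for this analysis (curated pG4 annotations, SNS-seq and
Repli-seq libraries) are large external datasets, so the package ships a
generator that emulates their statistical structure with full ground
truth. Its defaults are the package's standard study conditions, chosen
once to be realistic at desk scale and used by the test suite:

* Genome: 5 chromosomes × 2 Mb at 40% GC (uniform per base, optional
  linear gradient), with 60 GC-elevated CGI blocks (1.5 kb at 65% GC).
  This is large enough for stable enrichment statistics yet keeps a full
  run in minutes.
* Motifs: canonical pG4s planted at Poisson rates of 40 monomers and 10
  clusters per Mb, cluster sizes 2–6 with a decreasing distribution
  (0.50/0.25/0.12/0.08/0.05), intra-cluster gaps uniform on 1–100 bp.
  Planted entities are flanked by A/T and kept >100 bp apart so their
  category assignment is unambiguous; chance motifs arising in background
  sequence are legitimate detections and are audited against an
  independent scanner rather than suppressed.
* Origins: 400 per genome, 300 bp wide. An origin is placed adjacent to a
  random cluster with probability `q_c`, adjacent to a monomer with `q_m`,
  otherwise uniformly. `q_c` and `q_m` are solved analytically from the
  target log-odds ratios (defaults 1.5 and 0.5) and the genome's
  background hit probability `b` (the fraction of anchor positions within
  the association distance of a planted cluster/monomer):
  `q = (plogis(logOR + qlogis(b)) - b) / (1 - b)`. Placement is oriented
  3' of the cluster on its strand, so the strand-aware association holds
  by construction. True strengths follow an additive model (baseline 0.02
  reads/bp; +0.03 per clustered pG4, +0.005 per monomeric pG4, +0.02 in
  CGI).
* Marks: 70% of origin-associated clusters get a nucleosome-free region
  planted 5' of the cluster (the asymmetric pattern); H2A.Z peaks are
  placed near planted pG4 entities independent of origin status; both have
  uniform background peaks.
* Reads: SNS reads are Poisson per origin (`strength × length`) with
  uniform midpoints plus uniform background (0.002 reads/bp); Repli-seq
  windows follow a smooth sinusoidal early/late landscape per chromosome,
  with each window's reads split multinomially over S1–S4 (Gaussian kernel
  on the fraction index, spread 0.8) at ~30 expected reads per
  window-fraction. The "with" condition moves 20 percentage points of the
  late-fraction mass of a late-replicating locus to S1, so the expected RT
  shift is +40 by the formula.

What the generator does **not** emulate: sequencing errors, mappability
and GC amplification bias, spatially autocorrelated origin placement,
CpG-resolved island structure, or real pG4 sequence diversity (planted
motifs are canonical with A/T loops). Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery on data that
satisfies the model's assumptions — not robustness to the artifacts of
real libraries.

# Verification strategy

Every fast implementation is checked against an independent oracle:
interval merging against a transitive-closure union–find; motif detection
against a second regex engine applied to forward and reverse-complement
sequence; clustering against connected components of the pairwise gap
graph; the GLM log-odds ratio against the closed form `ln(ad/bc)`;
overlap flags, windowed counts and origin strengths against all-pairs
counting; strong-origin selection against sort-and-slice with ties.
Calibration is checked by parameter recovery at the standard study
conditions: planted log-odds ratios in {0, 0.5, 1.0, 1.5} covered by the
95% Wald interval in at least 90% of 200 re-randomizations per level;
the planted 20-point locus advance recovered as a mean RT shift within 2
points of +40 over 100 seeds; and the planted per-cluster strength effect
covered by its 95% CI in at least 90% of 200 read re-simulations.
Recovery replicates re-randomize origin placement, background sampling
and reads on a fixed motif landscape per level, which keeps the suite
within minutes on one CPU without changing the estimand.

# Known limitations

* The matched background pairs each random segment with one feature; it
  does not attempt joint moment matching of additional covariates (repeat
  content, chromatin state).
* Wald intervals on small tables (any cell < ~5) are approximate even
  with the continuity correction; the generator's defaults keep expected
  cells comfortably above that.
* The detector implements the canonical quadparser rule only; curated or
  experimentally derived motif sets can be supplied as BED and flow
  through every downstream stage unchanged.
* The RT-shift statistic consumes locus-level percentage vectors; deriving
  those vectors from windowed counts assumes the locus spans at least one
  full window midpoint.
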