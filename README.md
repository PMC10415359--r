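# g4origin

Genome-scale analysis linking **clustered G-quadruplex motifs (pG4s)** to
**DNA replication origins**.

Replication origins in vertebrate genomes are not defined by a consensus
sequence, but origin activity correlates with G-rich motifs able to fold
into G-quadruplexes. This package implements the computational side of
testing a sharper hypothesis: that the functional cis-signal is not a
single pG4 but a *cluster* — 2 to 6 same-strand pG4s less than ~100 bp
apart — while isolated (monomeric) pG4s are largely inert. It provides,
as composable R functions plus a pipeline:

- **pG4 detection** with the canonical rule `G{3,}(N{1,7}G{3,}){3}` on
  both strands, and **classification** of motifs into monomeric, clustered
  (k = 2..6, gap ≤ 100 bp, same strand) and oversize runs;
- **GC/size-matched random backgrounds**: every feature is paired with
  random segments of identical length in the same GC bin, the null model
  for enrichment;
- **logistic-regression enrichment**: for feature class *F*, segments are
  extended ±1 kb around their anchor and flagged for overlap; the
  log-odds ratio of the flag between real and matched random segments is
  the enrichment statistic, logOR = ln(ad/bc) with
  se = √(1/a + 1/b + 1/c + 1/d) and a two-sided Wald test, plus a
  strand-aware origin variant (pG4[+] upstream / pC4[−] downstream of the
  origin peak);
- **anchored coverage profiles** (20-bp windows, 10-bp step, ±1 kb) and
  **origin strength** (SNS reads per bp; top-25% "strong" origins;
  stratification by CGI status and pG4 content with 95% t CIs);
- **Repli-seq timing**: 50-kb/10-kb windowed counts of four S-phase
  fractions, normalization by the asynchronous sample, standardization,
  cubic-spline smoothing, the weighted-average timing track
  `WA = 0.750·S1 + 0.583·S2 + 0.417·S3 + 0.250·S4` (higher = earlier),
  and the locus-level shift statistic `RT shift = −ΔL + ΔE`;
- a **synthetic-data generator** with full ground truth (planted motifs,
  origins realizing configured log-odds ratios, NFR/H2A.Z marks, SNS
  reads, Repli-seq counts with a planted local timing advance), so every
  stage is testable without external data.

Inputs are FASTA genomes and BED6 feature/read files; outputs are BED,
TSV, bedGraph and a JSON run report. Intervals are 0-based half-open
everywhere.

## Worked example

A fully synthetic run with known ground truth:

```r
library(g4origin)

cfg <- sim_config(n_chroms = 2, chrom_length = 500000,
                  n_origins = 100, n_cgis = 12, seed = 42)
sim <- simulate_dataset(cfg)

motifs <- detect_pg4(sim$genome)
cl <- cluster_pg4(motifs)
cl
#> pG4 classification: 70 motifs; 9 clusters; 41 monomers; 0 oversize runs
#> fractions: monomeric 0.586 / clustered 0.414 / oversize 0

rnd <- sample_matched_random(sim$origins, sim$genome, seed = 42)
keep <- setdiff(seq_len(nrow(sim$origins)), rnd$unmatched)
fr <- overlap_flags(sim$origins[keep, ], cl$clusters, genome = sim$genome)
fn <- overlap_flags(rnd$segments, cl$clusters, genome = sim$genome)
logistic_enrichment(fr, fn)
#> enrichment: logOR = 0.8537 (se 0.5592), Wald z = 1.527, p = 0.127
#> counts: a = 11 b = 89 c = 5 d = 95

rt_shift(rt_percent_vectors(sim$repliseq$with, sim$repliseq$locus),
         rt_percent_vectors(sim$repliseq$without, sim$repliseq$locus))
#> RT shift = 36.88 (deltaE = 16.90, deltaL = -19.99); earlier
```

The logOR of 0.85 ± 0.56 estimates the planted origin–clustered-pG4
association (true value 1.5 at these conditions; a single 1-Mb genome is
deliberately small — the test suite shows calibrated 95% CI coverage over
200 replicates at the standard 5 × 2-Mb conditions). The RT shift of
+36.9 recovers the planted advance that moved 20 percentage points of the
locus's late-fraction signal into S1 (expected value +40, here at ~30
reads per window).

The full pipeline — simulate (or load BED/FASTA inputs), detect, cluster,
sample background, enrich, profile, strength, timing — runs as:

```r
run_pipeline(pipeline_config(simulate = sim_config(seed = 1), seed = 1),
             "out/")
```

or from a shell via `Rscript inst/scripts/g4origin.R run --outdir out`.
Every stage writes its output files and `report.json` records every
statistic with input checksums; reruns with the same seed are
byte-identical.

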