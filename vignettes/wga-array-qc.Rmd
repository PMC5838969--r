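---
title: "QC of mixed gDNA / wgaDNA SNP-array studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QC of mixed gDNA / wgaDNA SNP-array studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayqc)
```

# The problem

High-density Infinium-class SNP arrays want more genomic DNA than many
epidemiological collections can spare. Whole-genome amplification by
multiple displacement amplification (MDA, φ29 polymerase) multiplies the
template, but amplified DNA (wgaDNA) behaves differently from native DNA
(gDNA) on the array: call rates drop, and drop differently by biospecimen
source (buccal wash worst, blood and saliva-kit DNA similar); heterozygous
sites can lose one allele during amplification (allele drop-out);
chromosome ends under-amplify, so probes there fail in every wgaDNA sample;
and the Log R Ratio track is noisier, degrading copy-number inference.
`arrayqc` implements the QC battery that quantifies each of these effects
on a mixed-input study, and a synthetic-data generator that produces
Infinium-like output carrying these artifacts with known truth, so every
analysis operation is testable by parameter recovery.

# Data model and conventions

The pipeline works on three tables. The **manifest** describes probes
(probe id, locus id, chromosome, 1-based position, A/B alleles, window GC
fraction, CpG density); distinct probes assaying the same variant share a
locus id ("duplicate loci", ~1.5% of probes on real arrays). The
**sample sheet** describes samples (individual, input type, source
material, plate, chip with 4 samples, chip position, reported sex). The
**call table** holds one row per sample × probe: genotype class, GenCall-
style confidence score (GC score), raw intensities, LRR and BAF.

Conventions applied throughout:

* genotypes are stored A/B-relative (AA/AB/BB/NC), so concordance is
  strand-free; Final-Report allele pairs map to classes on read;
* a call is a no-call (NC) exactly when its GC score falls below the
  threshold (default 0.25);
* coordinates are 1-based inclusive; the 50-kb analysis windows are
  half-open `[start, start + 50000)` and genome-anchored at position 1
  (window of a locus = `floor((position - 1)/50000)`), not anchored at the
  first covered probe; BED output converts to 0-based half-open;
* the Final-Report dialect (header block, tab-separated columns Sample ID,
  SNP Name, Allele1, Allele2, GC Score, X, Y, Log R Ratio, B Allele Freq,
  4-decimal floats, `--`/`--` for no-calls) is declared by this package,
  since the vendor column set is configuration-dependent; readers are total
  on files the writers produce and report malformed rows by line number.

# Sample QC

Call-rate denominators are per input type: probes with no genotype in any
sample are removed from both denominators; probes additionally failing in
every wgaDNA sample are removed from the wgaDNA denominator. A sample's
call rate is its informative-probe count over its input-type denominator.
The pass boundary treats a rate of exactly 95% as passing ("less than
95%" fails). Chips where all 4 samples fail are excluded as systematic
errors; chips with 3 of 4 failing are flagged but retained, since a shared
upstream cause cannot be confirmed from the chip alone. Plates are flagged
when their failing fraction exceeds the cohort rate with a binomial tail
probability below 1e-4; plate exclusion remains a manual-review decision.

Heterozygosity is the AB fraction of called autosomal genotypes
(configurable; sex chromosomes are excluded by default to avoid
male/female structure). No standard outlier rule exists for this statistic,
so the package uses Tukey fences at `k = 3` (outside
`[Q1 − 3·IQR, Q3 + 3·IQR]`), with `k` exposed in `qc_config()`. Repeat
selection is the deduplicated union of call-rate failures and
passing-but-outlying-heterozygosity samples, each tagged with its reasons.

# Concordance

Replicate pairs are all unordered within-individual sample pairs, typed by
the two input types. Concordance is computed over probes called in both
samples; a mismatch is a different AA/AB/BB class. NC in either sample
removes the probe from that pair's denominator — the convention implicit in
call-rate-conditioned concordance reporting.

Duplicate-locus concordance aggregates **within sample first**: for a given
locus and input type, a sample contributes only if all the locus's probes
are called, and counts as concordant only if they all agree; the locus's
concordance is the fraction of such samples, and the 99% threshold
("greater than" = high) classifies loci into both-high / both-low /
low-in-one-type. The alternative aggregation (pooling probe pairs across
samples) differs only at third decimals here, but the order is fixed and
unit-tested because it changes what one sample with a single discordant
probe contributes.

MAF uses one sample per individual — gDNA preferred, then highest call
rate — because replicate samples would otherwise double-count alleles. The
B-allele frequency is `(n_AB + 2·n_BB) / (2·n_called)` folded to
`[0, 0.5]`.

# Locus QC

Probe failures have three classes: `failed_all` (no call anywhere),
`failed_wga_only` (no call in any wgaDNA sample, at least one gDNA call),
`ok`. A locus fails in a class only if **all** its probes do — the
conservative reading, since one working probe still yields genotypes.
Failing loci are counted per 50-kb window; "subtelomeric" is
operationalized as the terminal `k = 3` covered windows of each chromosome
(coverage ending mid-arm flags the last covered windows, since the probe
content defines what "chromosome end covered by probes" can mean). The
failure/GC association is the Pearson and Spearman correlation between the
window failure fraction and mean window GC, with a bootstrap percentile CI;
zero-variance inputs are reported as undefined rather than silently NA.

# LRR/BAF and wave normalization

From raw channel intensities, `theta = (2/π)·atan2(y, x)` and `R = x + y`;
the expected intensity at theta interpolates linearly between the
genotype-cluster centroids (flat beyond the outer clusters);
`LRR = log2(R / R_expected)`; BAF interpolates theta piecewise-linearly
between centroids, clamped to `[0, 1]`. `x = y = 0` is undefined and
emitted as missing.

The renormalization is a concrete, reproducible model chosen to deliver
the qualitative behaviour expected of GC-wave correction: (1) quantile
normalization of each sample's `R` to the cohort per-rank median (ties take
the mean of tied reference positions; the operation is idempotent against
its own output); (2) per-sample least-squares regression of LRR on centered
polynomial terms of window GC and CpG density (degree 2 by default — degree
1 cannot bend with the wave's curvature, higher degrees overfit sparse GC
tails; the degree is configurable and automatically lowered on
rank-deficient designs); (3) a per-chip rescaling factor: a multiplicative
intensity rescale is additive in log2, so it is carried by the regression
intercept and summarized per chip as `2^(mean intercept)`. Correction
subtracts the fitted wave (intercept included, so adjusted per-sample mean
is ~0). Genotypes and GC scores are never touched by normalization, and
BAF is not wave-corrected: the correction targets dosage, and empirically
barely moves genotype-conditional BAF spread. The per-sample BAF spread in
`sd_report()` is computed on residuals from the called genotype's cluster
mean (0, 0.5, 1), so the three-cluster geometry does not dominate the
statistic.

# CNV detection

Segmentation is circular binary segmentation: for a series of n values the
statistic of an arc `(i, j]` is the absolute difference of arc and
complement means scaled by `sqrt(1/k + 1/(n−k))` (the residual-sd factor is
permutation-invariant and omitted); the maximal arc is tested by permuting
the segment (default 1000 permutations in `cbs_segment()`, 200 in the
pipeline default; significance at p ≤ 0.01, with early stopping once
significance is unreachable); accepted splits recurse. Segments shorter
than 20 probes are merged into the neighbor with the closer mean — the
20-probe floor suppresses false discovery. The scan is vectorized by arc
length; the test suite proves it equal to an exhaustive double-loop oracle
on 100 seeded series.

Both the LRR series and the mirrored-BAF series are segmented and their
intervals intersected (which track the original analyses segmented is not
decisive; segmenting both captures dosage events and copy-neutral
imbalance). The mirrored-BAF series keeps heterozygous calls plus probes
with BAF inside `(0.15, 0.85)`, so hets displaced by mosaicism survive;
`mBAF = max(BAF, 1−BAF)`. Because informative probes are sparse (roughly
one per seven probes at typical heterozygosity), allelic evidence for an
interval is taken **locally** from the series inside the interval and
judged against the sample's baseline (series median) plus a margin of
0.05, rather than from broad segment means that dilute short events.

Classification defaults (all configurable, derived from canonical
Infinium expectations): gain at
`LRR ≥ +0.10` with elevated mBAF (a 3-copy het sits at BAF 1/3 or 2/3),
loss at `LRR ≤ −0.15` with mBAF ≈ 1, CN-LOH at neutral LRR with
mBAF ≥ 0.95 on real informative probes, mosaic CN-LOH at neutral LRR with
intermediate elevated mBAF and mosaic fraction `2·(mBAF − 0.5)` — a formula
exact for CN-LOH only, which is why gains and losses report no fraction. An
interval whose expected informative-probe count is substantial but which
contains none is a "het desert" and counts as complete allelic imbalance:
that is how a true deletion presents in single-sample data, where the
deleted hets are called homozygous. Full (non-mosaic) CN-LOH with no LRR
shift and no surviving hets is not claimable from single-sample evidence;
such intervals are flagged `undetermined` for manual review, mirroring
manual exclusion of unclear calls, and review-flagged intervals are
excluded from matched-pair accounting.

Matched-pair concordance takes the gDNA sample's events as reference: a
true positive requires same chromosome, same class and reciprocal overlap
≥ 50% (the field's standard interval-matching rule);
unmatched reference events are false negatives, unmatched test events
false positives, and the rate is `TP / n_reference`, aggregated by summing
counts across individuals. Samples whose post-normalization LRR sd exceeds
0.30 are excluded from CNV analysis as too noisy.

# The synthetic-data generator

The generator emulates, with full truth tables: a rare-variant-heavy MAF
spectrum; per-sample quality by source material and input type; GC-score
distributions tied to quality; locus-specific allele drop-out in wgaDNA;
complete and wgaDNA-only probe failures with subtelomeric concentration;
chip/plate systematic failures; per-sample GC/CpG waves and chip offsets on
LRR; injected CNV/mosaic events; and Identifiler-style STR profiles with
drop-out and contamination. Identical seed + config reproduces output
byte-identically; each generator draws from its own derived seed, so the
generators compose in any order.

Key calibrations (fixed once, from the study conditions the generator
emulates):

* **MAF mixture.** `maf = 0.5·Beta`, mixing a rare-heavy component
  `Beta(0.25, 8)` (weight 0.68) with a common component `Beta(1.4, 1.1)`.
  The weight solves `E[2p(1−p)] = 0.137`, the median autosomal
  heterozygosity of a rare-content-heavy array. Genotypes are HWE draws per
  individual; replicate samples share the individual's genotypes. No
  linkage disequilibrium is simulated — none of the QC metrics uses it.
* **Quality and GC scores.** Latent quality `q ∈ [0,1]` per sample is
  Normal per (input type × source) stratum, truncated to `[0.02, 0.98]`.
  GC scores are `Beta(μφ, (1−μ)φ)` with `μ = 0.3765 + 0.75·q`, `φ = 5`;
  the 0.25 no-call rule is applied downstream, not baked in. Under this
  model a sample crosses the 95% call-rate line near `q = 0.30`, and the
  stratum means/sds are set so the expected failure rates reproduce the
  gradient of a mixed-source study: wgaDNA buccal ≈ 25%, blood ≈ 9%,
  Oragene ≈ 7%; gDNA ≈ 3.5–4.2% everywhere. The buccal excess is large and
  recovered at any cohort size; the blood/Oragene gap (~2 points) needs
  cohorts of several hundred per stratum to resolve, which is why the unit
  test checks the full ordering on a sharper configured gradient.
* **Allele drop-out.** A small fraction (0.55%) of loci are drop-out-prone,
  each with a fixed weaker allele; a heterozygous wgaDNA call at a prone
  locus drops that allele with probability `0.8 + 0.3·(0.55 − q)`. Locus-
  specificity matters: independent per-call drop-out would make
  wgaDNA–wgaDNA replicates *less* concordant than gDNA–wgaDNA pairs,
  whereas locus-directed drop-out makes two amplifications fail the same
  way — reproducing the observed ordering gg ≥ ww ≥ gw (~99.99 / 99.97 /
  99.94%). The closed form `observed het = h·(1 − d)` and the gw
  concordance deficit `d·h` hold by construction and are verified by
  simulation.
* **Subtelomeres.** Each chromosome end is under-amplified with
  probability 0.5 ("nearly half of chromosome ends"); in affected ends the
  terminal 3 windows' loci fail all wgaDNA samples with probability 0.7.
  The per-locus magnitude of under-amplification has no established
  value, so the failure probability is a free, documented parameter.
* **Waves.** The injected LRR wave is
  `scale_s · (0.20·(gc − mean gc) + 1.0·(cpg − mean cpg))` plus a per-chip
  offset (sd 0.03) and Gaussian noise `0.12·(1 + (1 − q))` — noisier for
  poor samples, letting the CNV noise gate engage. The wave term is linear
  by construction, which the degree-2 regression provably removes; with
  these defaults waves are a small share of total LRR variance, so the
  corrected sd drops by only a few percent while remaining strictly lower
  for every sample.
* **Events.** Gains shift LRR by +0.32 with het BAF at 1/3 / 2/3; losses by
  −0.45 with hets collapsing to homozygous calls; mosaic CN-LOH leaves LRR
  neutral and splits het BAF to `0.5 ± m/2`. The imbalance direction at a
  locus is a property of the individual (shared across their replicate
  samples). Carriers are drawn from individuals with both input types so
  the matched-pair concordance surface has support at scaled-down cohort
  size, and each injected event is attenuated in a given wgaDNA sample with
  probability 0.1 — producing the false-negative excess that puts long-run
  matched-pair concordance near 90%.
* **STR profiles.** Truth profiles per individual (15 autosomal markers,
  uniform allele ladders, AMEL from reported sex); wgaDNA profiles inherit
  truth with quality-driven drop-out (`0.5·(0.5 − q)` per het marker) and
  marker failure (`0.3·(0.35 − q)`), plus third-allele contamination in 1%
  of samples. Quality categories (high / intermediate / poor) use invented,
  configurable cutpoints (≥ 15 concordant and 0 failures = high; ≥ 3
  drop-outs, ≥ 2 failures or contamination = poor) since no published
  binning exists.

What the generator does **not** emulate: linkage disequilibrium and
pedigree structure; raw two-color image artifacts and idat/GTC binary
formats; cluster-position mis-estimation (the cluster model is fixed and
shared, so LRR/BAF recomputation from simulated intensities is exact by
construction); dye-bias chemistry; population stratification; STR stutter
and electropherogram noise. Passing tests therefore demonstrate that the
analysis operations are correct and that parameters injected under this
model are recovered — not that the defaults match any particular real
cohort's error magnitudes.

# Numerical choices and degenerate inputs

Permutation p-values use the `(1 + exceedances)/(1 + permutations)`
estimator with early stopping; segmentation is deterministic given the
seed. Quantile normalization resolves ties by averaging tied reference
positions. The wave regression falls back to a lower degree on
rank-deficient designs (e.g. constant GC) with a warning. Correlation on
zero-variance windows is reported as undefined. A segmentation series
shorter than the minimum segment returns a single segment. Duplicate loci
with fewer than two probes are rejected; samples with zero called
genotypes, empty call tables and zero co-called pairs raise errors naming
the offending unit.

Problem sizes: the test suite runs on studies of roughly 24–400 individuals
and 400–3,000 probes, with 100-series oracle comparisons and 100-replicate
event-recovery suites; the acceptance script simulates ~350 samples × 4,000
probes. These sizes keep every distributional property measurable (binomial
error a few percent or less) while the full battery completes in minutes on
one CPU.

# Known limitations

* The mosaic-fraction formula is exact for CN-LOH only; gains and losses
  report no fraction.
* Full CN-LOH without mosaicism is undetectable from single-sample data by
  design; such intervals surface as review flags, not calls.
* The CBS scan is O(n²) per split; per-chromosome series beyond ~10⁵
  probes would want a compiled scan or windowed pre-thinning.
* Chip/plate failure modeling degrades latent quality uniformly; real
  systematic failures can have structure (e.g. position-on-chip gradients)
  that the detector would still catch but the generator does not produce.
* The STR quality cutpoints and the duplicate-locus aggregation order are
  declared package conventions; both are configurable and documented
  because no authoritative definition exists.
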