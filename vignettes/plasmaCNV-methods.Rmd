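---
title: "Tumor-only copy-number amplification calling from ctDNA panels: methods and design"
author: "plasmaCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plasmaCNV methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Circulating tumor DNA (ctDNA) is the tumor-derived subset of the cell-free
DNA (cfDNA) in plasma. In late-stage cancer patients for whom a tissue
biopsy is not feasible, hybrid-capture panel sequencing of cfDNA is often
the only route to genomic profiling. Somatic copy-number amplifications
(e.g. of *EGFR*, *ERBB2*, *MET* in non-small-cell lung cancer) are
clinically actionable but hard to detect in cfDNA because the ctDNA
fraction is frequently below a few percent: a 20-copy amplification at a
1% tumor fraction shifts the apparent copy number from 2.00 to only 2.18,
an 8% depth excess that is easily drowned by capture and library biases.

plasmaCNV implements a tumor-only calling scheme for this setting: no
matched white-blood-cell sample is required; instead, healthy-donor cfDNA
profiles serve as the error model.

## The pipeline

For one sample, per-probe mean coverage is taken through four stages:

1. **Median normalization.** Depths are divided by the sample-wide median
   (of the positive depths), removing total-yield differences. The
   normalized profile has median 1.
2. **Bias correction.** A combined model of the three per-probe covariates
   that dominate capture efficiency — GC fraction, probe overlap score,
   and mappability — is fitted on the per-probe *median* of the
   median-normalized healthy-donor profiles and divided out. The model is
   multiplicative: a loess curve in GC (degree 2, span 0.3, direct
   surface) times a linear term in overlap score and mappability. The two
   components are decoupled by backfitting (three alternating passes):
   fitted sequentially in a single pass, the smooth GC curve absorbs
   covariate structure through chance GC–covariate correlation and leaves
   a visible residual GC trend. After backfitting, predictions are
   rescaled so the median corrected training depth is exactly 1.
3. **Panel of normals (PoN).** Per probe, the median and a robust scale
   (1.4826 × MAD) of the bias-corrected donor profiles. Probes whose
   median is below `minDepth = 0.2` (median-normalized units) are
   excluded: low-coverage probes are the dominant source of false
   positives. The sample's log2 ratio at probe *j* is
   `log2(depth[j] / ponMedian[j])`; a zero depth is replaced by a
   pseudodepth (half the smallest positive depth of the sample) so a
   dropout yields a finite, strongly negative ratio rather than a masked
   probe.
4. **Segmentation and calling.** Per-probe log2 ratios are segmented by
   circular binary segmentation (below). With `sd_seg` the *population*
   standard deviation of the segment-level mean log ratios, the per-sample
   amplification threshold is `max(3 * sd_seg, 0.1)`; a gene is called
   amplified when its log2 ratio — the probe-count-weighted mean of the
   segment means overlapping its probes — is strictly above the
   threshold. Only gains are called; deletions are deliberately out of
   scope (at percent-level tumor fractions a single-copy loss is a 0.7%
   depth deficit, far below the noise floor, and ctDNA ploidy cannot be
   estimated reliably).

### Copy-number model

With tumor fraction $p$ and tumor-side absolute copy number
$\mathrm{ABCN}$, a gene's expected log2 ratio against a diploid reference
is

$$\log_2\!\mathrm{Ratio} \;=\; \log_2\frac{\mathrm{ABCN}\cdot p + 2(1-p)}{2},$$

inverted exactly by

$$\mathrm{ABCN} \;=\; \frac{2\,(2^{\log_2\!\mathrm{Ratio}} + p - 1)}{p},$$

floored at 0. The numerator of the first expression,
$\mathrm{ABCN}\cdot p + 2(1-p)$, is the **effective copy number** of the
dilution — the quantity a detection-limit experiment reports (a 60-copy
amplification at 0.3% tumor fraction is effectively 2.2 copies).

Tumor fraction $p$ is estimated from fragment length: ctDNA molecules are
shorter than cfDNA from normal cells, and the proportion of fragments
below 150 bp is taken as $p$. When $p = 0$ the amplification status is
still reported from the log-ratio rule, but ABCN is marked not evaluable
(the two outputs are separable). $p$ is clamped to $[0,1]$ and never
inflated, and no ploidy re-estimation is attempted.

### Circular binary segmentation

Per chromosome, the segmenter finds the arc $(i, j]$ of probes maximizing
the arc-vs-complement statistic

$$T(i,j) \;=\; \frac{|\bar{x}_{\mathrm{in}} - \bar{x}_{\mathrm{out}}|}
{s_p\sqrt{1/k + 1/(n-k)}},$$

with $s_p$ the pooled within-group SD, and splits when the permutation
p-value — probe values shuffled within the chromosome — falls below
`alpha = 0.01`, recursing on the pieces. Because the statistic is
symmetric in arc and complement, scanning $i < j$ covers the circularized
sequence. Numerical details that matter for reproducibility:

* Ties in the argmax are broken at the lexicographically smallest
  $(i, j)$; permutation exceedances are counted with a relative tolerance
  of $10^{-9}$ so that symmetric rearrangements (whose statistic is equal
  up to float error) count as exceedances.
* The permutation loop stops early once enough exceedances have accrued
  that $p \ge \alpha$ is certain (`ceiling(alpha * (nPerm + 1))`), which
  caps the cost of null segments at a few dozen permutations.
* Splits require at least 4 probes (the pooled variance needs 2 degrees
  of freedom); a 1-probe chromosome is its own segment; a pooled variance
  of 0 (constant values) gives statistic 0.
* The RNG is seeded per call (`seed = 1` by default) and the global RNG
  state is restored afterwards; runs are bit-reproducible.

The suite verifies the segmenter against an independently coded
brute-force oracle (naive $O(n^3)$ loops, same statistic and permutation
contract) on 200+ random instances of up to 15 probes.

Masked (PoN-excluded) probes are skipped: segments are runs over the
non-masked subsequence, `n_probes` counts contributing probes, and the
probe-count-weighted mean of segment means equals the mean of the
non-masked log ratios exactly (a conservation property the tests assert
at $10^{-9}$).

### Why a threshold *floor*, and a caveat about small panels

`3 * sd_seg` is degenerate for a flat single-segment profile
(`sd_seg = 0`); the floor of 0.1 keeps a flat profile call-free. The rule
also has a genuine small-panel artifact: an amplified segment contributes
to the SD that thresholds it. With $k$ segments of which one sits at mean
$m$ and the rest at 0, the population SD is $m\sqrt{k-1}/k$, so for
$k < 8$ a lone amplified segment can *never* exceed 3 SDs, and for
moderate $k$ mid-level amplifications are suppressed. This is one reason
the simulated detection limit for a 13-copy gene is worse than for a
60-copy gene even at equal effective copies, and it motivates running
each cell-line profile separately (as the dilution validation does) and
using a panel with tens of chromosome-level segments.

## The synthetic-data generators

The simulate module emulates the data the pipeline consumes; all
generators are deterministic given a seed, and each attaches its ground
truth (injected bias vector, mixture weight, per-gene copy numbers) for
parameter-recovery tests.

* **Panel**: 150 genes × 10 probes by default — the scale of the assay
  this pipeline targets — at 7 genes per chromosome (22 chromosomes).
  GC ~ Beta(20, 24) (mean 0.45), mappability ~ Beta(9, 1), overlap score
  ~ Gamma(2, 0.25). The three landmark spike-in genes (*ERBB2*, *EGFR*,
  *MET*) are placed on three different chromosomes so one gene's
  amplification cannot bleed into another's segment.
* **Donors**: `depth = targetDepth × bias(covariates) × LogNormal(0, σ)`
  per probe, with `targetDepth = 1000` (a desk-scale stand-in for the
  10,000× assay depth) and `σ = 0.05` (≈5% multiplicative probe noise
  after UMI deduplication — a realistic post-dedup CV for a targeted
  panel; Poisson counting noise at the simulated depth comes on top of
  it). The injected bias is
  `exp(-6 (gc - 0.35)²) × (1 + 0.6 (map - 1))`: a unimodal
  capture-efficiency curve peaking below the panel's typical GC, hence
  monotone — and visible as a depth–GC correlation — over most probes.
* **Cell lines**: the dilution validation uses two profiles mirroring the
  standard validation lines: ERBB2 = 60 copies (an HCC1954-like breast
  cancer line) and EGFR = 20, MET = 13 (an NCI-H1573-like lung
  adenocarcinoma line), from CCLE. A cell-line profile carries the same
  injected bias as the donors times `ABCN/2` per gene.
* **Spike-in**: depth-space mixing of median-relative profiles,
  `f × tumor + (1 - f) × background`, rescaled to the target depth with
  per-probe Poisson resampling. Depth space is the sufficient statistic
  for this pipeline; mixing reads would only add the Poisson noise that
  the resampling step injects directly, and keeps the experiment
  desk-scale.
* **Fragments**: lengths are rounded normals truncated to [50, 400] bp —
  a short tumor mode N(145, 10) and a long normal mode N(167, 10),
  consistent with published cfDNA fragmentomics — mixed with weight equal
  to the tumor fraction. The below-150 bp mass of each mode has a closed
  form against which the estimator's calibration (and its bias under
  overlapping modes) is tested.

### The in-silico detection-limit experiment

`runLodExperiment()` mirrors the dilution validation: for each of 3
replicate sets, a PoN is built from 4 freshly simulated donors, each
cell-line profile is mixed into a held-out donor at fractions
5%, 4%, 3%, 2%, 1%, 0.6%, 0.3%, and the full pipeline runs. A gene's LOD
is the smallest fraction at which it is amplified in **all** replicate
sets (the validation's replicate-consistency reading; a detection-rate
criterion would need many more replicates than three). Alongside, the
experiment reports the realized per-fraction thresholds, so the simulated
LOD can be compared with the analytic crossing — the smallest fraction
whose expected log2 ratio exceeds the realized threshold
(`analyticLodFraction()`). The two agree within one ladder step: at the
crossing fraction the expected margin is by definition small relative to
the gene-level noise, so the all-sets rule typically lands there or one
step above.

Under the default conditions the noiseless ladder reproduces detection
limits of 0.3% for the 60-copy gene and 1% for the 20-copy gene
(effective copies 2.2 at both), while the 13-copy gene stays below the
3-SD threshold of its own run across the ladder — the qualitative
ordering the dilution validation reports.

## What passing tests do and do not show

The generators emulate multiplicative probe bias, sample noise, counting
noise, and bimodal fragment lengths. They do **not** emulate: GC bias
that varies *between* samples (the fitted curve is per-PoN, not
per-sample), probe dropout patterns correlated with sequence context, UMI
errors, off-target capture, subclonal copy-number heterogeneity, or the
deviation of real cfDNA fragment-length distributions from truncated
normals (nucleosomal 10-bp periodicity). Passing the suite therefore
shows the pipeline's internal consistency and its behavior under the
stated noise model, not clinical performance; concordance against tissue
sequencing can only be established on real cohorts.

## Parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `minMapq` | 20 | MAPQ cutoff for depth counting |
| `minDepth` | 0.2 | PoN probe-exclusion threshold, median-normalized units |
| `span`, `nIter` | 0.3, 3 | loess span and backfitting passes of the bias model |
| `alpha` | 0.01 | CBS split level |
| `nPermutations` | 1000 | CBS permutations per split test |
| `thresholdFloor` | 0.1 | minimum amplification threshold, log2 units |
| `thresholdBp` | 150 | fragment-length cutoff for tumor fraction, bp |
| `maxSize` | 1000 | largest template length retained, bp |
| `targetDepth` | 1000 | simulated mean probe depth |
| `noiseSigma` | 0.05 | simulated lognormal probe noise (natural-log SD) |

Problem sizes used by the test suite: 1500-probe panels, PoNs of 10 (4
per replicate set in the LOD harness), 100 simulated samples for the
specificity property, 50 replicates for copy-number recovery, 200 random
instances for the segmentation oracle.

## Known limitations

* Coordinates are BED-style 0-based half-open throughout; panel files
  from 1-based sources must be shifted on import.
* The probe overlap score and mappability are accepted as panel-file
  inputs with documented semantics; they are not computed from a
  reference genome.
* Whether bias correction should precede or follow PoN division is not
  identifiable from first principles; this package corrects first, then
  divides (both the PoN training samples and the tumor sample pass
  through the same correction, so the choice mostly affects
  interpretability of the stored PoN).
* Tumor fraction from fragment lengths is a crude estimator: with
  overlapping modes it is biased by the normal mode's below-150 bp mass
  (the tests quantify this against the closed form), and a
  variant-allele-frequency blend, where available, would be preferable.
* The 3-SD rule's small-panel artifact discussed above.
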