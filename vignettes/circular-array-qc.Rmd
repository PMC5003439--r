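---
title: "Circular quality-control plots for probe-level microarray batches"
author: "qccircos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular quality-control plots for probe-level microarray batches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why quality control before normalization

Normalization forces all arrays of a batch onto a common intensity
distribution, which is exactly the wrong thing to do to an array that is
broken: a degraded, badly hybridized or mislabeled array should be
identified and removed *before* its values are blended into the batch.
`qccircos` computes the classic per-array quality measurements for
Affymetrix-style PM/MM probe data, condenses them to outlier flags, and
draws the whole batch in a single circular figure in which every array is
one sector and every quality family one concentric rim. The figure scales
from half a dozen arrays to a hundred or more, because an outlier is a red
dot regardless of batch size, and the output is SVG, so any region can be
magnified without loss. A set of Circos-compatible karyotype/track/
configuration files is emitted alongside for users who prefer to run the
external Circos renderer on the same data.

```{r, eval = FALSE}
library(qccircos)
gen <- generate_batch(cluster_scenario_spec(seed = 1))
dir <- tempdir()
paths <- write_synthetic_dataset(gen, file.path(dir, "data"))
cfg <- run_config(paths["annotation"], paths["intensities"], paths["manifest"],
                  out_svg = file.path(dir, "qc.svg"),
                  out_circos = file.path(dir, "circos"),
                  out_report = file.path(dir, "report.tsv"))
report <- run_pipeline(cfg)
report
```

## The measurements

**Zonal background and noise.** The chip is divided into `grid_k × grid_k`
(default 4 × 4) equal rectangular zones by probe coordinates. In each zone
the lowest `ceiling(low_fraction · n)` intensities (default 2%) estimate
the optical floor: the zone background is their mean and the zone noise
their standard deviation. The array values are unweighted zone means.
Both are dataset-relative diagnostics: an array whose background or noise
is far from the batch median is suspect.

**Detection calls.** For a probe set with pairs $(PM_i, MM_i)$ the
discrimination scores $R_i = (PM_i - MM_i)/(PM_i + MM_i)$ are tested
against $\tau = 0.015$ with a one-sided Wilcoxon signed-rank test of
$H_1: \mathrm{median}(R) > \tau$. The p-value is exact — the null
distribution is enumerated over sign assignments (a dynamic programme
over doubled midranks, equivalent to the $2^k$ enumeration) — for up to
12 informative pairs, and a tie-corrected, continuity-corrected normal
approximation beyond. Calls are Present ($p < 0.04$), Marginal
($0.04 \le p < 0.06$), Absent otherwise. Spike-in transcripts are added
at hybridization and must read Present on a good array; a Marginal call
already counts as a failure for flagging, which is deliberately
conservative.

**Housekeeping 3′/5′ ratios.** β-actin and GAPDH are long, ubiquitously
expressed transcripts probed at their 5′, middle and 3′ ends. Labeling
starts from the 3′ end, so degraded RNA inflates
$\mathrm{median}(PM_{3'}) / \mathrm{median}(PM_{5'})$. The ratio is taken
on the raw scale because QC precedes normalization. An array is flagged
when the ratio is *strictly greater than 3* (more than threefold
induction).

**Poly-A controls.** Up to four polyadenylated bacterial transcripts
(dap, lys, phe, thr) spiked before labeling monitor the labeling
reaction. Their signal is $\log_2(\mathrm{median}\, PM)$; an array is
flagged when the signal is a robust outlier across arrays *or* the
detection call is Absent.

**RNA degradation slope.** Mean $\log_2 PM$ intensity is computed per
5′→3′ probe position over all probe sets with exactly $k = 11$ PM probes
(the dominant design on this chip family), anchored so position 1 maps
to 0. The degradation statistic is the OLS slope of this profile against
position. We fit the slope on the *shifted but unscaled* profile, in
log2-intensity units per position, so that it estimates an injected
linear trend directly; the regression t-statistic is reported as the
scale-free companion, and an SE-standardized profile
(divided by the pooled standard error $\sqrt{\mathrm{mean}(se_j^2)}$,
with scale 1 substituted when the SE is exactly zero) is kept for
display. Scaling the slope itself by the SE would turn it into a pure
signal-to-noise quantity that shrinks with probe-set count and could not
be compared against a trend in intensity units.

**Normalization and PCA.** PM intensities are quantile normalized with
*no background adjustment* (each column's sorted values are replaced by
the row-wise mean of the column-sorted matrix; ties receive the mean of
the reference values at their tied ranks, which makes the result
permutation-stable), log2 transformed (values below $2^{-20}$ are clipped
before the log), and summarized per probe set by two-way median polish
(≤ 10 sweeps, absolute stopping rule: summed |row + column adjustments|
< 0.01; expression = overall + column effect, excluding probe effects).
Each probe-set row of the expression matrix is then centred to mean zero
and the matrix decomposed by SVD; the arrays' PC1 scores go on the outer
rim, and an array far from every cluster of scores is a candidate
outlier. Sign convention: the largest-magnitude element of each
probe-side loading vector is positive, which fixes the otherwise
arbitrary reflection. Rows (probe sets), not columns (arrays), are
centred; variance fractions are $d_i^2 / \sum d^2$.

## Condensing to flags

Dataset-relative metrics (background, noise, poly-A signal, degradation
slope) are flagged by a robust dispersion rule: value $v$ is an outlier
iff $|v - \mathrm{median}| > k \cdot 1.4826 \cdot \mathrm{MAD}$ with
$k = 2$. When the MAD degenerates to zero the rule falls back to
$|v - \mathrm{median}| > k \cdot \mathrm{IQR}/1.349$ using inverse-ECDF
(type-1) quantiles — the type matters: for a sample like (5, 5, 5, 6) the
type-1 IQR is exactly 0, so near-constant batches flag nothing rather
than flagging the one slightly different value. If both spreads are zero,
nothing is flagged. Absolute rules are used where the science provides
one: housekeeping ratio > 3, spike call ≠ Present.

The upstream tools this pipeline mirrors ship fixed "suggested cut-off"
ranges that are not published as numbers; a dataset-relative robust rule
is reproducible, works at any intensity scale, and can mimic a fixed
cutoff by adjusting `robust_k` in the configuration. The cost is that
with very few arrays (say 6) the MAD is itself noisy and borderline
arrays can pick up isolated flags; this matches how such batches behave
in practice and is why the flags are descriptive, not inferential — no
multiplicity correction is applied across rims.

## The circular figure

Rims, outer to inner: **1** PC1 scores (all arrays' scores repeated
inside every sector, min–max scaled to the rim's radial band; the
sector's own array is a larger red dot, the others smaller blue dots),
**2** one tile per array colored by degradation (piecewise-linear
blue–white–red anchored at the minimum, median and maximum slope;
zero-range input maps to white), **3** background and noise dots, **4**
β-actin and GAPDH, **5** three spike-ins, **6** up to four poly-A
controls. Red = flagged, blue = clean, grey = metric unavailable (e.g. a
manifest without the thr control). Sectors are equal-width, laid
clockwise from 12 o'clock, and ordered by ascending degradation slope
(ties broken by array name) so arrays of similar RNA quality sit side by
side. Rendering is purely deterministic string assembly: the same report
produces a byte-identical SVG.

The Circos export writes one `chr` segment of 1000 abstract units per
array, a scatter file for rim 1 with $n^2$ rows (every score in every
sector), a tile file with `fill_color=r,g,b` per array, highlight files
for rims 3–6, and a master configuration `circosQCconfig.txt` that
references the data files by relative path. Coordinates are 0-based and
end-exclusive.

## The synthetic generator

Real probe-level data for this platform ships in a proprietary binary
format, so validation uses a generator whose defects are known exactly.
The PM model on the log2 scale is

$$\log_2 PM = \text{baseline} + \text{probeset} + \text{probe} +
  \text{signature} + b \cdot (j - \tfrac{k+1}{2}) + \varepsilon,$$

with per-probe-set levels $\sim N(0, 1)$, per-probe affinities
$\sim N(0, 0.25)$, measurement noise $\varepsilon \sim N(0,
\texttt{noise\_sd\_log2})$ and $b$ the injected degradation slope. MM
probes carry half the PM signal; for an "absent" spike-in the MM instead
tracks PM to within a $U(0.9, 1.1)$ factor, which centres the
discrimination scores on zero and flips the call. On the raw scale every
probe receives additive optical background $N(bg, (0.1\,bg)^2)$ — tying
the fluctuation to the level makes average noise co-vary with average
background, as on real scanners. Cluster structure is a ±1 expression
signature of magnitude `cluster_offset_log2` over 20% of the probe sets
(a global shift would be erased by quantile normalization). Housekeeping,
spike-in and poly-A probe sets carry no probe affinities and no
degradation trend, and have 10 PM/MM pairs instead of 11, so the injected
ratio/level/state is exactly recoverable and the control sets stay out of
the degradation profile. "Noiseless" means `noise_sd_log2`,
`probe_sd_log2` and background all zero; in that limit every estimator
(slope, ratio, poly-A level) returns the injected value exactly.

What the generator does *not* emulate: spatial artifacts and scratches,
probe-sequence (GC) effects, saturation, and the heavy tail of real probe
affinity distributions (real spreads are wider than 0.25 log2 units; a
wider spread mostly inflates position-mean standard errors). Passing
tests therefore demonstrate the estimators and the flag logic, not
robustness to every physical failure mode of a scanner.

## Validation experiments and their sizes

These are the experiments run by the test suite and
`scripts/acceptance.R`; sizes were chosen to give stable rates at
desk scale.

* **Detection-call exactness** — 200 random PM/MM inputs, $k$ = 3–10,
  compared against explicit enumeration of all $2^k$ sign assignments.
* **Quantile normalization** — 100 random 500 × 8 matrices; sorted
  columns must coincide exactly and per-column ranks be preserved.
* **Median polish** — additive matrices recovered with zero residuals;
  random 11 × 8 matrices reach residual row/column medians ≤ 0.01 within
  10 sweeps.
* **Slope recovery** — 100 batches, 4 arrays, 200 probe sets,
  `noise_sd_log2 = 0.2`, injected slopes 0.10–0.25, background 0 (additive
  background compresses log2 slopes by $s/(s+bg)$ — a property of the
  measurement scale, so the recovery experiment isolates the degradation
  axis); every slope within 10% relative error in ≥ 95% of batches.
* **Flag recovery** — 50 ten-array batches from
  `defect_scenario_spec()`: one all-defect array (background 500 vs.
  clean 100 ± 50, slope 1.5 vs. 0.05–0.25, housekeeping ratio 5, all
  spike-ins absent, poly-A levels −3 log2) among clean arrays whose
  parameters follow evenly spaced bounded spreads. The spreads are chosen
  so that in *measured* space each injected defect sits at ≥ 5 robust SD
  of the clean arrays while no clean array can reach the 2-robust-SD flag
  threshold; flags must equal the injected truth on every rim in every
  batch. Truth labels are the documented flag rules applied to the
  injected parameters themselves; the noise sub-metric has no injected
  truth axis (noise is derived from background in the generator) and is
  reported but not part of the recovery comparison. The all-defect array
  must show the 2+2+3+4 = 11 red dots on rims 3–6 with at least one
  fully clean array showing none.
* **Cluster structure** — six-array batches
  (`cluster_scenario_spec()`: clusters of 3 and 2 plus one failed array
  with its own signature) in which within-cluster PC1/PC2 distances are
  smaller than between-cluster ones and the failed array is separated
  from every clean array.

## Numerical choices and degenerate inputs

* Zero-sum PM/MM pairs are dropped before the signed-rank test; zero
  differences $R_i = \tau$ are dropped before ranking; midranks for ties.
* A perfectly linear degradation profile has zero residual variance; the
  t-statistic is reported as `+Inf` with a `zero_residual` marker rather
  than failing.
* Intensities are serialized with 17 significant digits so file
  round-trips are bit-exact; report, SVG and Circos outputs are
  deterministic functions of their inputs.
* Single-array inputs: quantile normalization warns and returns the
  identity; the color gradient maps to white; the layout devotes the full
  circle to one sector.
* Coordinates are 0-based; chip geometry defaults to the coordinate
  bounding box unless a `# geometry:` pragma declares it.

## Known limitations

Binary CEL files are not parsed — an external converter to the documented
TSV formats is the path for real data, and the control-probe naming of a
given platform is supplied through the manifest rather than hardcoded.
The housekeeping flag reads "induced more than threefold" as a 3′/5′
ratio criterion; an absolute-expression reading would need a reference
level the raw data does not provide. Additive background biases raw-scale
log2 slopes and ratios toward zero, so degradation measures should be
compared within a batch, not across scanners with different optical
floors. With fewer than ~8 arrays the MAD-based flags lose resolution and
isolated borderline flags appear; with fewer than 3 arrays, no
dataset-relative flags are issued at all.
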