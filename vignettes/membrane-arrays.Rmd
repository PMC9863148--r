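---
title: "Methods: from scanned membrane to consensus marker panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from scanned membrane to consensus marker panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blotgrid)
```

This vignette is the package's account of its methods: the models behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic-membrane generator does and does not emulate, and
the numerical and design choices made where more than one reasonable
option existed.

## The measurement problem

A dot-blot antibody membrane prints capture antibodies as duplicate spot
pairs in a lattice of blocks; after incubation with a pooled biofluid
sample (here: pooled urine from CKD patients or healthy controls, per
gender), bound analytes produce chemiluminescent spots. The scanned raster
is the only quantitative record. Three things make the analysis harder
than ordinary microarray processing: the grid's absolute position varies
from scan to scan; membranes differ in overall exposure; and with pooled
designs there is exactly one membrane per biological condition, so the
only replication is the duplicate spot pair.

## Grid inference

The semi-automatic grid pipeline assumes only that (i) spots are roughly
Gaussian blobs brighter than background, (ii) bright reference (control)
spots occupy the corner positions of the printed grid, and (iii) the
printed geometry — blocks, per-block rows/columns, pitch, and the
alleyways between blocks — is known (`array_layout`).

**Blur.** `gaussian_blur(sigma = 4)` suppresses pixel noise before peak
finding. The convolution is separable with reflective boundaries and a
kernel truncated at 6 sigma, which keeps total intensity conserved and
makes consecutive blurs compose like a single blur of combined width to
about `1e-6` relative accuracy — a property the tests exercise directly.
Densities are *never* measured on the blurred image; blurring is for
localization only, so no signal mass is redistributed into the aperture
measurements.

**Maxima.** `find_local_maxima` reports peaks whose prominence — height
above the highest saddle connecting them to higher ground, with the
global minimum as sea level for the top peak — reaches a threshold, with
a minimum Euclidean separation between reported peaks. Small plateaus
(spots centered exactly between pixels, saturated spot tops) are reduced
to one deterministic representative and refined to half-pixel positions;
otherwise a 3-point parabolic fit refines each peak to sub-pixel accuracy.
The prominence threshold is a free parameter of the method (the noise
tolerance of interactive peak finders). The generic default is 10% of the
image dynamic range; the pipeline wrapper `fit_spot_grid` uses 1% instead,
because a membrane's dynamic range is dominated by its brightest
(near-saturating reference) spots, so a small fraction of it still sits
far above the blurred read noise while keeping dim analyte spots
detectable. Spots dimmer than the threshold are not lost — their grid
positions fall back to interpolation.

**Corners and interpolation.** Each image quadrant contributes one corner
anchor: the maximum-intensity point among the three maxima nearest the
image corner. This relies on the corner reference spots being bright,
which holds for the near-saturating positive-control spots that
commercial membranes print. All layout positions are then placed by
bilinear interpolation of the four anchors at fractional grid coordinates
in pitch units, where spots within a block sit one unit apart and the
step across a block boundary is `1 + alley` units — the alley is the
extra gap on top of the regular pitch. (A formulation in which the
cross-block step equals `alley` units alone would degenerate at
`alley = 0`, with adjacent blocks sharing a lattice line.) Bilinear
interpolation with four anchors reproduces translation, scale and shear
exactly; full perspective correction is deliberately out of scope.

**Snapping.** Grid entries move to the nearest detected maximum within
`0.4 · pitch`, greedily by ascending distance and one-to-one, so two
entries can never collapse onto one bright maximum; unmatched entries
keep interpolated coordinates and are tagged as such. The operation is
idempotent.

## Densitometry and duplicate QC

`integrated_density` sums original pixel intensities over pixels whose
centers lie within `spot_radius` of the grid position. Pixel-center
membership makes the measure exactly additive and homogeneous in the
image, which the tests verify; at the default radius of about three spot
sigmas the aperture captures ≥ 98% of a Gaussian spot's mass. No local
background ring is subtracted — the detection rule below handles
background globally.

A printed spot can simply fail. Such a dropout measures bare background
at a position no maximum supported, and with only two duplicates it
would otherwise wreck both the duplicate variance and the ratio.
`flag_dropouts` marks a duplicate as missing only when three conditions
coincide: interpolated provenance, density at or below the background
threshold, and at least one duplicate of the same analyte above the
threshold. The last condition is essential — a consistently dim duplicate
pair is a real measurement of a lowly expressed analyte (possibly a
down-regulated marker) and must be kept. After flagging, the surviving
duplicate carries the analyte (single-survivor rule); an analyte with no
surviving observation in a condition becomes unevaluable rather than a
fake ratio.

## Normalization

Membranes differ in development and scan exposure by an overall factor
(and possibly mild nonlinear shape differences). `robust_spline_normalize`
maps each sample's log2 quantiles onto the across-sample mean quantile
curve through a monotone Hermite spline fitted at quantile anchor points.
Two choices matter and are worth stating plainly:

* **Few, interior anchors.** The default is 11 anchors spanning the
  15%–85% rank range. Membrane panels are small (tens of analytes), so a
  fine-grained map would chase the sampling noise of individual order
  statistics; and anchoring the extreme ranks would *pin* the dimmest and
  brightest analytes onto the reference quantiles, erasing exactly the
  fold changes a differential analysis is after (regulated analytes live
  at the extreme ranks).
* **Unit-slope extension.** Beyond the anchored range the map continues
  with slope 1 in log2 — a pure offset. For sample-to-sample scale
  factors this is exact, and it leaves the fold changes of extreme-rank
  analytes untouched. The simulator's per-membrane exposure factor is
  removed exactly by this map (verified: calls are invariant to the
  exposure magnitude).

The map is monotone, so within-sample ranks are preserved exactly; zeros
are offset by half the smallest positive value before the log transform.

## Detection against the background spot set

A membrane's background spots are those with density at or below
`min + 0.05 · (max − min)` (inclusive at the threshold; the minimum
always qualifies). Reference anchors are excluded from the rule in the
pipeline since they are synthetic bright controls. Each analyte's
duplicates are then tested one-sided against the background densities,
excluding the analyte's own positions from the comparison set.

The test is a pooled-variance two-sample t. The relevant null hypothesis
is that a blank spot is just another draw from the background noise
distribution — under that null pooling is exactly calibrated, whereas the
Welch–Satterthwaite approximation with n = 2 duplicates is markedly
anti-conservative (one-sided size near 0.08 at α = 0.05, by Monte
Carlo). The Welch variant remains available (`var_equal = FALSE`), and
with a single surviving replicate a z-score against the background mean
and SD is used. With zero background variance the call degenerates to an
exact comparison of means.

## Moderated t, FDR, and the composite call

With one pooled membrane per condition, duplicate spots are the only
replication; they are technical replicates and the inference is
correspondingly about measurement reproducibility, not biological
variance — a structural limitation of pooled designs that no statistic
can undo, and the reason the workflow leans on cross-series replication
(below).

Per analyte, the two-group model gives a residual variance `s2_g` with
`d_g` degrees of freedom. The prior `(d0, s02)` is estimated by
closed-form moment matching on `log(s2_g)` (digamma correction, trigamma
inversion by Newton's method), the posterior variance is
`(d0*s02 + d_g*s2_g) / (d0 + d_g)`, and the moderated t uses `d0 + d_g`
df. Two limits anchor the implementation: `prior_df = 0` reproduces the
ordinary pooled-variance two-sample t exactly, and `prior_df = Inf` with
a fixed `prior_var` gives the fixed-variance statistic. When the moment
equation has no positive solution (homogeneous variances) the prior df is
infinite and the posterior variance is the `d_g`-weighted pooled common
variance, making identical variances a fixed point of the shrinkage. The
tests cross-check the full estimator against the `limma` reference
implementation on matched inputs.

P-values are BH-adjusted within each contrast (one series, one gender),
matching per-contrast marker tables. The composite call requires, at
once: detection at α = 0.05 in at least one condition, a normalized
linear ratio above 1.5 (up) or below 0.667 (down), moderated-t p < 0.05,
and FDR < 0.25. Ratios are computed on the normalized linear scale
(means over duplicates), the t on log2 values. Analytes missing any
statistic are flagged unevaluable and called `ns`.

## Consensus panels

`consensus_across_series` intersects two series' call sets, keeping only
analytes called in the same direction; analytes called in *opposite*
directions are reported in a discordant slot, never silently dropped —
series-to-series reversals are a documented feature of pooled-membrane
data and belong in the output. `gender_overlap` applies the same logic
across genders within a series. `mean_gender_calls` averages male and
female CKD values per duplicate (densities are averaged before the ratio
is computed, not ratios averaged) and re-runs the standard calling
against the controls; its detection p for the averaged condition is the
smaller of the two gender p-values, since an analyte present in either
gender is present in the mean. Sample dendrograms use `1 − Pearson r`
distance with complete linkage (heights are the linkage distance at each
merge) and export to Newick.

## The synthetic-membrane generator

`simulation_config` defaults encode the emulated study design: two
experiment series × {male, female} × {CKD, control}, one pooled-urine
membrane per arm; 50 analytes printed in duplicate on a 2×2-block,
10×10-per-block membrane (pitch 16 px, alley 2 pitch units, aperture
radius 5 px, 600×400 px 16-bit images); log-normal baselines
(log2 ~ N(10, 0.8)); planted markers of 4 up- and 4 down-regulated
analytes at 3-fold, plus 2 discordant analytes that flip direction
between series (emulating observed series-to-series reversals);
technical duplicate CV 15%; Gaussian spot PSF sigma 1.7 px; corner jitter
SD 2 px (a bilinear warp of the whole grid); per-spot jitter SD 1 px;
10% missing duplicate spots; constant background 50 with read noise
SD 3; near-saturating reference anchors (peak 20000), as on real
chemiluminescence membranes; and a per-membrane exposure factor
(log2 SD 0.5) scaling signal, background and noise together. A fixed
seed reproduces every image and truth sidecar byte for byte.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: spatial illumination gradients and
flat-field artifacts, saturation and blooming of strong spots,
non-Gaussian spot morphology (comets, rings, merged neighbours), membrane
rotation beyond what bilinear corner warping captures, antibody
cross-reactivity, and any biological subject-level variance (pooling is
modeled implicitly as one membrane per arm). The tabular shortcut
`simulate_expression_table` mirrors the image path's quantified output
(spot mass + aperture background term + aperture-summed read noise)
without rendering rasters, for fast statistical calibration runs.

## Problem sizes and numerical choices

The shipped tests validate grid recovery on 20 simulated membranes
(aggregate fraction of positions within 2 px of planted centers),
detection calibration on 50 simulated tables each for the null and the
SNR-10 case, full-pipeline marker recovery on 8 simulated studies, BH
against a brute-force step-up oracle on 1000 fuzzed vectors, and
clustering against a brute-force agglomeration oracle on 200 random
matrices — sizes chosen so the whole suite completes in about a minute
while keeping the binomial error of each estimated rate a few percent.
The acceptance script re-simulates smaller batches (6 membranes, 25
calibration tables, 4 studies) for the same quantities.

Remaining numerical conventions, for completeness: BH adjustment
delegates to `stats::p.adjust` (the brute-force double-loop formula lives
in the tests as an oracle); trigamma inversion starts at `0.5 + 1/y` and
iterates Newton steps to relative `1e-10`; maxima ties are broken by
descending intensity then (y, x) order; dendrogram ties follow
`stats::hclust`; grid-snapping ties resolve by ascending distance; and
16-bit quantization rounds and clamps at write time so write/read round
trips are pixel-identical.

## Known limitations

Corner detection requires a detectable reference spot in each image
quadrant — a membrane cropped so tightly that a quadrant has none fails
loudly rather than guessing. The duplicate-pair replication structure
cannot separate technical from biological variance. The normalization's
trimmed anchoring assumes fewer than roughly a third of analytes are
regulated in one direction; panels violating that would need
invariant-set anchoring. And the detection test's pooled variance is
calibrated for the blank-spot null; its p-values for strongly expressed
analytes are presence calls, not abundance inference.
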