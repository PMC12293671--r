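---
title: "Quantifying the superficial capillary plexus: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the superficial capillary plexus: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octamorph)
```

This vignette explains what each stage of the package computes, why the
defaults are what they are, and what the synthetic validation does and
does not demonstrate about real data.

## The imaging model

An en-face angiogram is a square grayscale raster with a physical
calibration: the nominal acquisition is a 4.5 mm field sampled at
320 px, i.e. a pixel pitch of 14.06 µm. Intensities are min–max rescaled
to [0, 1] on load (a flat image maps to zero; the export bit depth of
device software is not standardized, so [0, 1] min–max is this package's
convention and is stated here so binarization is bit-reproducible). RGB
input collapses to Rec. 601 luminance. Geometry uses 0-based pixel
coordinates with pixel centres at integer + 0.5; every mask operation
(polygon containment, disc crops, centroids) is evaluated at pixel
centres, which keeps area bookkeeping unambiguous.

## FAZ morphometry

The foveal avascular zone arrives as a polygon (drawn manually in
clinical practice) and is rasterized by the centre-inclusion rule; a
centre exactly on an edge counts as inside. No smoothing or snapping is
applied — the outline is consumed as given.

* **Area** is the foreground pixel count times the squared pitch.
* **Perimeter** is the traced Moore boundary chain, axis steps weighted 1
  and diagonal steps √2, times the pitch. The raw (1, √2) chain length
  overestimates smooth digitized contours by ≈5% on average over
  orientations — on a radius-150 disc it yields a circularity of 0.90
  rather than 1 — so the default estimator applies the classical Kulpa
  calibration π(1+√2)/8 ≈ 0.948. With it, disc circularity is 1.004 at
  radius 150 px and converges to 1 with radius. `weights = "chain"`
  returns the uncalibrated chain length.
* **Circularity** is 4π·area/perimeter², dimensionless and
  scale-invariant; rasterization makes small shapes read slightly high
  (a radius-10 disc reads ≈1.07), which is why irregularity comparisons
  should be made at matched scale.
* Degenerate single-pixel contours report 4 × pitch with a warning;
  multi-component masks are reduced to the largest component with a
  warning that is also surfaced as a flag in the per-eye record.

**Axial-length adjustment.** The instrument's lateral scale assumes a
reference eye; true dimensions scale with the Littmann–Bennett ocular
magnification `q(AL) = 0.01306 (AL − 1.82)`. Lengths are multiplied by
`q(AL)/q(AL_ref)` (reference 24.39 mm by default, configurable), areas
by its square. The source workflow names no formula, so this choice is
an explicit, documented assumption; circularity and the wall-to-lumen
ratio are ratios of lengths and are invariant. Only FAZ area and
perimeter (and the AO length metrics) are adjusted — the density metrics
are dimensionless fractions and are reported unadjusted.

## The analysis region

A disc of 3 mm diameter is centred on the FAZ centroid and the FAZ mask
is subtracted; the remainder (≈34,600 px at nominal calibration) is the
denominator of both density metrics. Where the disc extends past the
frame it is clipped, the clipped fraction is reported, and metrics are
computed on the clipped region — the alternative (refusing the eye)
would discard data the operator can judge for themselves. A
`denominator = "full_disc"` option keeps the FAZ pixels in the
denominator for comparison with pipelines that do not mask the FAZ.

## Vessel enhancement and binarization

**Frangi vesselness.** Per scale σ, the image is smoothed and its Hessian
computed with separable sampled Gaussian-derivative kernels (truncated at
4σ, second-derivative kernel re-centred to zero mean so constants give
exactly zero), γ-normalized by σ². With eigenvalues ordered
|λ₁| ≤ |λ₂|, the response is zero where λ₂ ≥ 0 (bright vessels), else
`exp(−R_B²/2β²)(1 − exp(−S²/2c²))`. Defaults: σ ∈ {1, 1.5, 2, 2.5} px —
capillaries at 14 µm/px span roughly 1–3 px — β = 0.5, and c adaptive at
half the per-scale maximum of S (with an absolute floor so numerically
flat images stay zero). The final map is the maximum over scales, so
adding a scale never lowers any pixel. All parameters are exposed.

**Inversion.** The original display pipeline inverts the vesselness map
before thresholding; computationally, thresholding v or 1−v are mirror
decisions. This package binarizes the vesselness map directly
(foreground = high vesselness) and keeps `invert_vesselness()` as an
explicit optional stage for fidelity.

**Phansalkar thresholding.** For each pixel, with m and s the mean and
standard deviation over a square window of radius R (edge-replicated
padding, computed with an integral image), the threshold is
`T = m(1 + p·e^(−qm) + k(s/r − 1))` and a pixel is foreground iff its
value is strictly greater than T (ties to background). Defaults are the
published ones for low-contrast images: R = 7 px, k = 0.25, r = 0.5,
p = 2, q = 10. Window statistics use the full window even across the
region boundary — restricting them would bias thresholds near the FAZ —
and the region constraint applies to the output only. The optimized
implementation is tested bit-identical against a per-pixel brute-force
oracle.

## Perfusion metrics

* **Vessel density** — binarized vessel pixels over the effective area.
* **Skeletonization** — sequential directional thinning that deletes
  border pixels that are 8-simple (by a 256-entry lookup table built from
  brute-force component counting) and not curve endpoints. Because every
  deletion is individually topology-preserving, component and hole
  counts are preserved exactly, the skeleton is contained in its input,
  and the operation is idempotent. Residual 2×2 blocks (X-crossings of
  four diagonal arms, where no pixel is simple) are resolved by a local
  connectivity-preserving rewiring constrained to the original mask.
* **Vessel length density** — skeleton pixels over the effective area.
  Pixel count is the common convention for skeleton density on rasters;
  a √2-weighted chain length is available (`skeleton_length`) but off by
  default.
* **Fractal dimension** — boxes of side ε ∈ {2, 4, 8, …, frame/4},
  anchored at the foreground bounding-box origin (no offset averaging);
  FD is minus the least-squares slope of log N(ε) vs log ε, and the fit's
  R² is reported with a warning below 0.95. The power-of-two ladder with
  a fixed anchor makes reference objects exact: a frame-spanning line
  gives 1.000 and a depth-6 Sierpinski triangle gives 1.58496. For
  *space-filling* objects the upper sizes must stay small relative to
  the object — boxes comparable to a disc's radius inflate boundary
  counts and bias the slope to ≈1.86 — so the 2-D reference check
  measures a radius-200 disc with ε ≤ 16 via the exposed `box_sizes`
  argument. FD of the measured skeleton is computed on the skeleton
  restricted to the effective region, consistent with the FAZ masking.

## AO wall morphometry

The text definition "ratio of wall thickness to lumen diameter" is
ambiguous between one and two wall thicknesses; the published group
values are consistent only with the two-wall convention
`WLR = (TVD − LD)/LD = 2·WT/LD` (control means 100.341/81.085 µm give
0.2375 ≈ the printed 0.237, where WT/LD would give 0.119). The two-wall
convention is implemented and the discrepancy documented here.
Parameters are derived per ROI and then averaged — the mean of per-ROI
ratios, not the ratio of mean diameters, matching the stated protocol —
and the axial-length adjustment reuses the Littmann–Bennett factor
(lengths ×q-ratio, WCSA ×q-ratio², WLR invariant). Whether manufacturer
software exports already-corrected values is unknown, so the adjustment
is optional.

## Cohort statistics

Shapiro–Wilk is applied per group (the branching rule speaks of *all
groups* being normal, which supports per-group testing) at α = 0.05;
ANOVA + Tukey (Tukey–Kramer standard errors for unbalanced groups) when
every group passes, Kruskal–Wallis (tie-corrected) + Dunn otherwise.
Dunn's z uses mean ranks of the pooled sample with tie-corrected
variance; adjusted p-values are Bonferroni over the k(k−1)/2 pairs
capped at 1, emulating the "multiplicity adjusted" Dunn output of common
statistics software, with Holm available. All tests are two-sided; no
variance-homogeneity gate is applied and no correction is made across
parameters. Spearman's ρ is the Pearson correlation of average ranks
with a two-sided t-approximation p-value (adequate at n ≈ 40; the t
approximation is asymptotic, so for very small n an exact approach would
be preferable). Constant groups make Shapiro–Wilk undefined and route to
the rank branch with a warning.

## The synthetic generators

**Vascular phantoms.** The FAZ boundary is a radial Fourier perturbation
of a circle (harmonics 3–8, RMS relative amplitude = the irregularity
knob), giving controllable ground-truth circularity; mean radius
0.268 mm matches a healthy FAZ area of ≈0.226 mm². Seed vessels enter
from the frame edges and random-walk with momentum (heading noise
SD 0.2 rad/step), branch with probability 0.06/step, and never enter the
FAZ; strokes are dilated to a 3-px caliber (~42 µm) and growth stops
when coverage of the disc-minus-FAZ region reaches the target (default
0.35, the healthy superficial-plexus scale) within ±0.01. The intensity
image is the mask blurred at σ = 0.8 px plus additive Gaussian noise
(SD 0.05), clipped to [0, 1]; truth masks are returned pre-noise.
Everything is a deterministic function of the seed.
`degrade_phantom()` deletes a seeded fraction of segments and optionally
re-draws the FAZ boundary at higher amplitude — the severity knobs that
emulate capillary dropout and FAZ irregularity.

What the phantoms do **not** emulate: OCTA speckle and decorrelation
noise, projection artifacts, motion artifacts, vessel caliber
heterogeneity, and the real plexus' space-filling regularity. Passing
the recovery tests therefore shows the pipeline is correct and
well-behaved on controlled inputs, not that its absolute outputs match
any instrument's.

**Cohorts.** One row per eye with the study's group sizes
(17/14/18/20), each metric drawn from a truncated Gaussian at its
group's mean and SD; truncation enforces metric domains (densities in
[0, 100]%, FD in [1, 2], BCVA in (0, 1]), and draws are rejected only at
the domain bounds, so means are unbiased (the control-group FD mean over
400 seeded cohorts reproduces 1.771 within 0.002). Cross-metric
correlations within an eye are not modelled — marginals are all the
published tables provide — with one deliberate exception: lumen diameter
and wall-to-lumen ratio are the independently drawn AO quantities and
TVD, WT and WCSA are derived from them, so the wall identities hold
exactly per eye and the WLR group separation matches its reported
distribution (deriving WLR from independent TVD and LD draws would
inflate its variance several-fold and destroy the group pattern). ROI
triplets are emitted with centred 2-µm jitter so ROI means reproduce the
per-eye diameters exactly.

## Known limitations and numerical choices

* At the default enhancement/threshold parameters the binarization
  recovers vessel *cores*: measured VD sits ≈0.08–0.10 below the drawn
  ribbon coverage at target density 0.35, stably across seeds (Dice
  ≥ 0.7 against truth; a global cut on the vesselness map recovers the
  drawn coverage, so the bias belongs to the local threshold). Measured
  VD is strictly monotone in the generated density, so group *contrasts*
  are preserved; absolute VD is parameter-dependent, as is generally
  true of threshold-based OCTA densities.
* Property tests that are scale-free (skeleton thinness, dropout
  monotonicity, determinism) run on 192-px phantoms; full-frame 320-px
  phantoms are used wherever calibration matters. These sizes are the
  package's validation choices.
* Flat-image rescale maps to zero; Phansalkar ties break to background;
  box counts are asserted non-increasing in ε; the FD fit requires at
  least 4 sizes.
* The statistics stage treats eyes as independent (one eye per patient
  in the target design); no mixed models or eye-within-patient
  clustering.
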