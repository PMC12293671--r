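# octamorph

Quantification of the retinal superficial capillary plexus from en-face
OCTA angiograms, and arteriolar wall morphometry from adaptive-optics
diameter measurements, with the cohort-level statistics used to compare
diabetic-retinopathy severity groups.

## What it computes

**FAZ morphometry.** From a manually delineated foveal avascular zone
polygon: area by pixel counting (`A = N · pitch²`), perimeter by Moore
boundary tracing with calibrated chain-code weights, and the circularity
index

```
Circularity = 4π · area / perimeter²
```

(1 for a perfect circle, lower for irregular shapes). Area and perimeter
are optionally adjusted for ocular magnification with the
Littmann–Bennett factor `q(AL) = 0.01306 · (AL − 1.82)`, relative to a
configurable reference axial length (default 24.39 mm).

**Perfusion metrics.** Inside a 3-mm disc centred on the FAZ centroid
(FAZ excluded): vessels are enhanced with a multiscale Hessian (Frangi)
filter,

```
V = exp(−R_B² / 2β²) · (1 − exp(−S² / 2c²)),   R_B = λ₁/λ₂,  S = √(λ₁²+λ₂²)
```

binarized with Phansalkar local thresholding
`T = m·(1 + p·e^(−q·m) + k·(s/r − 1))`, then reduced to vessel density
(VD, foreground fraction), a topology-preserving skeleton, vessel length
density (VLD, skeleton fraction) and the box-counting fractal dimension
(FD, slope of log N(ε) vs log ε).

**AO wall morphometry.** From total vessel diameter (TVD) and lumen
diameter (LD) per region of interest: wall thickness `WT = (TVD−LD)/2`,
wall-to-lumen ratio `WLR = (TVD−LD)/LD`, wall cross-sectional area
`WCSA = (π/4)(TVD²−LD²)`; parameters are derived per ROI, then averaged
over the three ROIs of a vessel.

**Cohort statistics.** Per parameter: Shapiro–Wilk normality gate, then
one-way ANOVA (+ Tukey) or Kruskal–Wallis (+ Dunn with Bonferroni-adjusted
p-values), plus Spearman rank correlation.

Synthetic generators (`generate_vascular_phantom`, `generate_cohort`)
produce seeded angiogram phantoms with ground-truth masks and per-eye
cohort tables with the study's group structure, so every stage can be
validated without patient data.

## Worked example

```r
library(octamorph)

ph  <- generate_vascular_phantom(phantom_spec(seed = 42))
rec <- run_octa_eye(ph$image, ph$truth$faz_polygon, eye_id = "phantom42",
                    group = "control", axial_length_mm = 23.7)
print(rec)
#> OCTA eye record 'phantom42':
#>   FAZ: area 0.2264 mm^2, perimeter 1.6971 mm, circularity 0.9879
#>   VD 0.2708, VLD 0.0943, FD 1.4556 (effective area 34596 px)
```

The phantom drew a healthy-scale FAZ (~0.226 mm²) and a capillary bed
covering 34.8% of the analysis disc; the pipeline recovers the FAZ
geometry almost exactly, and the binarized vessel map yields VD, VLD and
FD on the scales seen in superficial-plexus studies (the local threshold
recovers vessel cores, so VD sits below the drawn ribbon coverage — see
the vignette).

```r
tab <- generate_cohort(cohort_spec(seed = 42))   # 69 eyes in 4 groups
cmp <- run_cohort(tab, parameters = c("fd", "wlr"))
print(cmp)
#> fd                       F(3, 65) = 15.79, p = 8.1e-08
#>     control vs PDR: p adj = 8.006e-06 (tukey)   ...
#> wlr                      F(3, 65) = 9.633, p = 2.396e-05
#>     control vs PDR: p adj = 7.239e-06 (tukey)   ...
```

Fractal dimension and wall-to-lumen ratio separate the control and PDR
groups — the qualitative pattern the statistics stage is designed to
detect.

```r
derive_wall_metrics(100.341, 81.085)
#> AO wall metrics (1 ROI):
#>   TVD 100.34 um, LD 81.08 um, WT 9.628 um, WLR 0.2375, WCSA 2743.8 um^2
```

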