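---
title: "Quantifying the choriocapillaris from averaged en face OCTA: models and methods"
author: "CCvoid authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the choriocapillaris from averaged en face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CCvoid)
```

## The problem

The choriocapillaris is the anastomosing capillary monolayer directly behind
Bruch's membrane that supplies the outer retina and RPE. On en face OCT
angiography (OCTA) it appears as a bright meshwork interrupted by dark *flow
voids* -- regions with no detectable flow signal. A single en face frame is
dominated by speckle and signal dropout and looks granular; registering and
averaging 4--9 repeated frames restores the continuous meshwork and makes
quantification meaningful. The standard per-eye metrics are the **number**,
**total area** (mm^2) and **mean size** (um^2) of flow voids, and the
**vessel diameter index** (VDI), the average vessel caliber computed as total
vessel area divided by total vessel (skeleton) length. Regions containing
major retinal vessels and the foveal avascular zone (FAZ) are excluded.

CCvoid implements that pipeline end to end -- quality gating, SCP-driven
registration, averaging, Phansalkar binarization, exclusion masking,
component metrics and VDI -- together with a cohort-statistics layer
(Pearson and age-adjusted partial correlations, Levene-gated t tests,
age-group summaries, per-year trends) and a synthetic-data module that makes
every stage testable without any device export.

## The per-eye pipeline

### Quality gating

Frames carry the device signal-strength score (0--10); frames scoring below
8 (configurable, `min_quality`) or flagged with blink/fixation artifacts are
discarded. We read "scores more than 8/10" as *at least 8*: the phrasing is
ambiguous in the field's reports (often a translation of an inclusive
bound), and the cut is exposed as a config knob so either reading is one
keystroke away. An eye with fewer than 4 surviving frames is marked
excluded, with the reason carried through cohort accounting -- exclusion is
data, not an error.

### Registration

The superficial capillary plexus (SCP) frames drive registration: they carry
high-contrast landmarks, while the choriocapillaris slab is low-contrast and
noisy. Transforms are estimated on the SCP against a reference frame (the
highest quality score, ties to the first acquired) and applied to both
channels. The model is translation-only phase correlation: between repeated
scans at fixed scan geometry, residual eye motion is dominantly
translational. Subpixel refinement re-evaluates the correlation surface from
the cross-power spectrum on a 0.02-px grid around the integer peak
(matrix-multiply DFT upsampling); on synthetic stacks the recovered shifts
are within about 0.15 px of the injected ones, comfortably inside the 0.5-px
contract the tests enforce. Frames whose post-alignment correlation with the
reference falls below `registration_floor` (default 0.2) are dropped with a
warning.

Aligned frames are resampled bilinearly; pixels whose source fell off canvas
are *masked, not zero-filled*, so the average at the margins is an unbiased
mean over fewer frames.

### Averaging

The averaged image is the pixelwise mean over valid contributions. No
per-image histogram stretch is applied: inputs are in [0, 1], so the mean is
too, and local thresholds stay comparable across eyes. On synthetic stacks
the contrast-to-noise ratio against the true perfusion map rises
monotonically with frame count.

### Binarization

Flow voids are separated from vessels with the Phansalkar local threshold,
designed for exactly this kind of low-contrast image. For each pixel, over a
circular window of radius $R$:

$$t = \mu_w \left(1 + p\,e^{-q\,\mu_w} + k\left(\frac{\sigma_w}{r} - 1\right)\right)$$

with $\mu_w$, $\sigma_w$ the local mean and standard deviation. A pixel
strictly below $t$ is void; ties go to vessel (integer-quantized images hit
ties, so the rule is stated explicitly). Borders use reflective padding.
$k = 0.25$, $r = 0.5$, $p = 2$, $q = 10$ follow the method's original
values. The window radius is the one genuinely open parameter: we default to
15 px (150 um at 10 um/px, several intercapillary distances -- large enough
to see both phases, small enough to track slab inhomogeneity) and treat it
as required configuration. Thresholds are computed on the *unmasked* image
and the exclusion mask is applied afterwards, which keeps window statistics
unbiased near mask borders.

### Exclusion mask

Major retinal vessels are segmented from the SCP image (global Otsu
threshold, then a morphological opening that removes structures narrower
than the 30-um caliber cutoff, then a 2-px safety dilation against
projection-artifact halos). The FAZ is modeled as a central disc of 250-um
radius; FAZ delineation is commonly manual, so a user-supplied mask can
replace the automatic one. Masks covering more than half the field trigger a
warning rather than silent acceptance.

### Quantification

Flow voids are 8-connected components of the void map restricted to the
analyzable region; vessels are implicitly 4-connected, an asymmetry that
avoids paradoxical adjacency at diagonal contacts. Components that straddle
the mask are clipped, not dropped -- dropping would bias against large voids
near the FAZ. The minimum component size defaults to 1 px (no filtering),
configurable because related work filters speckle-sized voids.
`mean_size * count = total_area` holds exactly per eye by construction. The
VDI divides the vessel pixel count by the skeleton pixel count
(Zhang--Suen topology-preserving thinning) and is reported in pixels, the
unit most consistent with the dimensionless-looking values reported for
this metric; multiplying by the pixel pitch gives um.

## The synthetic-data module

### Meshwork ground truth

The capillary network is generated as the edge set of a Voronoi tessellation
of random lobule seeds: a pixel is perfused when the difference between its
distances to the second-nearest and nearest seed falls below an edge-band
threshold. This yields an anastomosing, fully connected lobular network;
the lobule interiors become the flow voids. Defaults: 300 px at 10 um/px
(the 3 x 3-mm macular field), 205 seeds/mm^2 (~70-um lobule spacing, the
macular lobule scale), void fraction 0.11 (about 1 mm^2 of voids per
9 mm^2, the healthy-macula regime). When no explicit vessel width is given,
the edge-band threshold is set by quantile so the realized void fraction
hits the target exactly; an explicit width takes precedence (a saturating
width gives zero voids rather than an error). The pristine image is
two-level, 0.15 background / 0.85 perfused: optical blur belongs to
acquisition, not to the tissue, and a two-level truth makes the zero-noise
pipeline exactly recoverable -- a property the tests assert.

What the generator deliberately does **not** emulate: the real flow-void
count density. Matching the reported ~206 voids/mm^2 at an 11% void
fraction requires lobules so fine (2--3 px at 10 um/px) that any pipeline
with subpixel resampling inflates their area past the 10% recovery
tolerance the module guarantees. The imaging truth therefore carries fewer,
larger voids, and the *cohort* generator (below) carries the reported count
scale instead. Passing imaging tests consequently show metric recovery on
lobule-scale geometry, not on the finest real-world granularity.

### Acquisition degradation

Each of the 4--9 frames is built as: per-pixel dropout of perfused signal
(before noise, so averaging provably recovers the perfusion support), a
Gaussian PSF (sigma 0.5 px, roughly the device's lateral resolution relative
to 10-um sampling), a random translation (|dx|, |dy| <= 6 px), and
multiplicative log-normal speckle with unit mean (sigma 0.15). A shifted
frame samples real tissue beyond the nominal field, as a real scan does: the
truth canvas is reflect-padded and each frame is a translated crop. Frame 1
carries zero shift and the top quality score, making it the reference and
anchoring the registered canvas to truth coordinates. The speckle scale is
the calibrated quantity: it keeps a single frame visibly granular (a naive
single-frame binarization over-reads the void area by >50%) while six-frame
averaging brings the flow-void area within 10% of truth, the module's
stated recovery guarantee. SCP partners are a distinct synthetic plexus --
wider lobules, capillary calibers below the 30-um major-vessel cutoff so a
healthy SCP is not flagged as major vessel -- imaged under the same motion.

### Cohort twin

The cohort generator is a linear-Gaussian statistical twin of a healthy-eye
cohort (n = 81 by default): age and axial length from truncated normals,
SFCT normal; total void area and mean size linear in age, VDI linear in
SFCT, count independent of age (an optional count-SFCT slope defaults to 0
because the corresponding reported association has no printed effect size).
Intercepts and residual SDs are derived algebraically from the published
marginal means/SDs and per-year slopes:

* intercept = marginal mean − slope × covariate mean
  (e.g. 0.99 − 4.20e-3 × 59.5 = 0.740 mm^2),
* residual SD = sqrt(marginal SD^2 − (slope × covariate SD)^2)
  (e.g. sqrt(0.20^2 − (4.20e-3 × 16.2)^2) = 0.188 mm^2).

Truncated covariates are **moment-matched**: the underlying normal is solved
(two-parameter root find on the closed-form truncated moments) so the
truncated distribution has exactly the requested mean and SD. Naive
truncation of N(59.5, 16.2) to [20, 90] would realize mean 58.7 and SD 14.6
and shift every age-linked statistic. The [20, 90] age window follows
plausible recruitment and the youngest-pictured-subject age of 22.

Because the published statistics are rounded, they are not perfectly
mutually consistent: the slope-implied age correlation of total area is
slope x SD(age) / marginal SD = 0.340, not the printed 0.336. The generator
is parameterized by the slopes and SDs, so its implied correlation is 0.340
and the replicate-average r comes out near 0.338 (small-sample r bias at
n = 81) -- inside two Monte-Carlo SEs of the printed value at 1000
replicates, which is the comparison the acceptance suite makes.

## Statistical layer

Pearson r with two-sided p from the t distribution on n − 2 df; partial
correlation as the correlation of least-squares residuals with n − 2 − k df;
Levene's test (center = mean, the classic form -- the unqualified "Levene's
test" of the field's reports) gating Student vs Welch t tests; and the
age-adjusted sex comparison as the group-coefficient p from
`value ~ sex + age`. An ANCOVA-style model is used there because a partial
correlation is ill-defined for a binary grouping analyzed by t tests; this
is a documented divergence from a literal reading of the methods it mirrors.
All p-values are two-sided at alpha = 0.05 with no multiple-testing
correction, matching standard practice in this literature. Age-group
summaries use the bins [20, 40), [40, 60), [60, inf); empty bins are
reported as missing, never zero.

## Numerical choices and degenerate inputs

* Thresholding ties go to vessel; the threshold window uses an explicit
  Euclidean disc and symmetric padding.
* Registration search is capped at 20 px; the correlation floor (0.2) drops
  structureless frames; frame counts are re-checked after every drop.
* Zero-variance inputs to correlation/trend functions error rather than
  returning NaN; zero residual variance after adjustment errors; collinear
  covariates error via a QR rank check.
* Zero flow voids yield count 0, total area 0 and a *missing* mean size;
  an empty vessel map makes the VDI an error (undefined), not a zero.
* Residual SDs of 0 are legal in the cohort generator (the degenerate
  noise-free model); covariate SDs must be positive.
* Random draws happen in a fixed documented order under one seed, so every
  generator is bit-reproducible; `simulateCohort(seed = NULL)` consumes the
  caller's RNG stream for replicate studies under one outer seed.

## Problem sizes used by the test and acceptance suites

The suites run the imaging stages on 160--192-px eyes (1.6--1.9 mm fields)
rather than the 300-px default, and the statistical calibrations on 500--2000
replicate cohorts (type-I error on 2000); these sizes give Monte-Carlo
resolution well inside every asserted tolerance. The cohort-recovery
comparison uses 1000 replicate cohorts of n = 81, the study-scale
configuration.

## Known limitations

* The imaging truth is lobule-scale (see above); absolute void counts from
  the image pipeline are not comparable to device-scale reports, while void
  area, size ordering and VDI behavior are.
* Registration is rigid translation; rotational or deformable residuals are
  not modeled or corrected.
* The FAZ stand-in is a centered disc; real FAZ geometry is irregular and
  should be supplied as a mask when available.
* The Phansalkar radius in published work is rarely reported; results are
  sensitive to it, which is why it is surfaced as required configuration
  rather than buried.
* The cohort twin is linear-Gaussian; it reproduces first and second
  moments and the printed correlation structure, not distributional shape,
  non-linear age effects, or inter-eye correlation (one eye per subject is
  enforced).
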