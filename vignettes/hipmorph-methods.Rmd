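---
title: "Hip morphometry from landmark outlines: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hip morphometry from landmark outlines: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmorph)
```

## The measurement problem

Cam morphology (an aspherical lateral femoral head), pincer morphology
(acetabular over-coverage) and acetabular dysplasia (under-coverage) are
candidate morphological risk factors for hip osteoarthritis. On a 2-D hip
image annotated with an ordered 85-point outline of the left proximal femur
and acetabulum, three quantities capture them:

* **Alpha angle (AA).** A circle of best fit is placed on the femoral-head
  outline points 15–28. Walking from the superior head toward the neck, the
  *departure point* is where the bony contour first leaves this circle. AA is
  the angle at the head centre between the femoral neck axis and the
  direction to the departure point. Cam morphology is defined as AA ≥ 60°.
* **Lateral centre-edge angle (LCEA).** The angle at the head centre between
  the vertical (perpendicular to the image x-axis) and the lateral acetabular
  edge, outline point 78. Pincer morphology is LCEA ≥ 45°; acetabular
  dysplasia is LCEA < 25°.
* **Minimum joint-space width (mJSW).** The minimum distance between the
  acetabular polyline (points 78–84) and the femoral-head polyline (points
  22–31), in millimetres.

Osteophytes are recorded as shaded areas (mm²) at three sites — lateral
acetabulum, superolateral femoral head, inferomedial femoral head — and
converted to ordinal grades 0–3 by thresholds calibrated with ROC analysis
against semi-quantitatively read grades. JSN grade is obtained the same way
from height-adjusted mJSW (smaller adjusted mJSW, higher grade). Radiographic
hip OA (rHOA) is grade ≥ 1 JSN together with a grade ≥ 1 osteophyte at any
site; the stricter "rHOA grade ≥ 2" requires grade ≥ 2 of each. The
association layer then fits logistic regressions of each outcome (rHOA,
per-site osteophytes, JSN, hip pain) on each morphology, sex-stratified and
combined, unadjusted and adjusted for age, height, weight and ethnicity
(plus sex in combined models).

All coordinates live in a canonical left-hip frame: superior = +y,
lateral = −x. Readers of imaging exports with other conventions should
normalise before constructing `landmark_set` objects.

## Geometric estimators and their numerical choices

**Circle of best fit.** `fit_circle()` minimises the sum of squared *radial*
residuals Σ(‖pᵢ − c‖ − r)². A closed-form algebraic (Kasa) fit provides the
starting point; Gauss–Newton iterations on the geometric residuals refine it
(step-norm tolerance 10⁻¹⁰ mm, at most 100 iterations). The result is
invariant to point order and equivariant under rigid motions; collinear or
sub-3-point inputs raise a degenerate-geometry error. The tests verify the
optimum against a derivative-free Nelder–Mead search of the same objective.

**Neck axis.** The published measurement protocol says only "a line through
the centre of the femoral head and neck"; the exact construction of the neck
centre is not public. `estimate_neck_axis()` uses a documented stand-in: the
neck centre is the midpoint of the minimum-width cross-section between the
superior and inferior neck boundary sub-polylines (template-configurable
index ranges, defaults 47–60 and 1–10, which the synthetic generator
realises). On a symmetric neck this midpoint falls exactly on the true axis.
This is a stand-in, not the original authors' rule — one reason the package
ships a generator with known ground truth rather than claiming replication
of any particular cohort's values.

**Departure point and tolerance.** "Leaving the circle" needs a numerical
definition. The scan runs from the last head-circle index (28) toward the
neck, and a departure is the first scanned point whose radial distance
exceeds `radius * (1 + departure_tolerance_frac)` — default tolerance 2% of
the radius (0.5 mm on a 25 mm head) — sustained for at least `min_run = 3`
consecutive scanned points (a run truncated by the scan end counts). The
crossing is linearly interpolated between the last interior and first
exterior points, giving sub-landmark resolution. The `min_run` requirement
changes nothing on noiseless outlines, where a genuine cam bump keeps
growing once it crosses the tolerance, but suppresses isolated spikes when
landmarks are noisy: a single-point rule would turn any ~0.5 mm upward
fluctuation anywhere along the scan into a spurious departure far from the
true junction. Spherical heads whose scanned points never leave the band
raise a `hip_no_departure` condition; `measure_hip()` records these as
AA = NA with `departure_flag = FALSE`, keeps them for LCEA-based analyses
and counts them in the log (they are excluded from cam analyses, and
`classify_morphology()` treats them as cam-absent).

**LCEA sign.** Negative LCEA (edge medial to the vertical) is allowed, for
robustness in extreme dysplasia, even though ordinary cohorts only show
positive values.

**mJSW.** The minimum over all vertex-to-segment distances between the two
polylines, taken in both directions — symmetric in its arguments, zero when
the polylines touch, and verified in tests against a dense-sampling oracle.

## Grading and classification

`calibrate_threshold_roc()` scans every midpoint between consecutive sorted
unique values and returns the cutpoint maximising Youden's J
(sensitivity + specificity − 1); a closest-to-(0,1) criterion is available
behind an argument. Ties are resolved to the midpoint of the first
contiguous optimal interval, so perfectly separable classes yield the centre
of the separating gap. "ROC analysis" alone does not pin down an operating
point; Youden's J is the conventional choice and is stated here explicitly.

Grades are inclusive at cutpoints: with osteophyte cutpoints (1, 4, 9) mm²
an area of exactly 4 mm² is grade 2. For JSN the comparison is mirrored
(adjusted mJSW at or below a cutpoint reaches that grade) — lower joint
space must never lower the grade. Grade monotonicity in both directions is
property-tested.

"Height-adjusted mJSW" is implemented as a sex-specific linear residual
shift: `adjusted = mjsw − slope_sex × (height − mean_height_sex)`, with the
slopes fitted on the calibration cohort (`fit_height_adjustment()`). A zero
slope is the identity. This is a documented stand-in for an unpublished
adjustment rule.

The numeric cutpoints used by the original study are not public; the
defaults in `default_grading_config()` are synthetic values matched to the
synthetic generator's area and mJSW distributions and should be replaced by
ROC calibration against a semi-quantitatively graded subset whenever one
exists.

## The association suite

`fit_logistic()` wraps base R's IRLS (`glm.fit`, relative deviance
tolerance 10⁻⁸, 50 iterations). Odds ratios are exponentiated coefficients
with Wald 95% intervals and two-sided Wald p-values; whether the original
analyses used Wald or profile intervals is unknown, and nothing downstream
depends on the choice. For a binary exposure without covariates the fitted
OR equals the 2×2 cross-product ratio, which the tests assert to 10⁻⁶
relative error, and "CI excludes 1 exactly when p < 0.05" holds cell-wise by
construction.

Suite conventions:

* Ethnicity enters one-hot with White as the reference (the dominant
  category); constant covariate columns in a stratum are dropped.
* Missing data are handled complete-case per model, with `n_used` reported
  per cell.
* Per-cell p-values carry no multiplicity correction, matching the
  presentation style of the descriptive tables the suite mirrors.
* Degenerate cells (single-class outcome or exposure) are emitted as flagged
  `skipped_single_class` rows; apparent separation (|β| > 15 or SE > 10) is
  flagged rather than silently reported. Firth-style penalisation is
  deliberately not applied by default.

Two sensitivity analyses mirror the main suite:
`run_sensitivity_restricted_reference()` compares pincer and dysplasia
against hips with LCEA in [25°, 45°) only, and `run_pain_attenuation()`
refits the cam→hip-pain model adding each osteophyte-presence indicator and
all three together, exposing attenuation of the cam OR when pain runs
through osteophytes.

Repeatability uses Cohen's kappa (with percent agreement) for
classifications and Lin's concordance correlation coefficient, computed with
population (1/n) moments, for continuous re-measurements.

**Rounding for display.** Prevalence percentages are rounded in two stages —
to two decimals and then to one, each half away from zero. Single-stage
rounding differs on ratios that land just below a half (e.g. 519/3382 =
15.346% → 15.35 → 15.4); the two-stage convention reproduces the reference
descriptive tables exactly and is applied uniformly via `round_half_away()`.

## What the synthetic generator emulates

`generate_hip_outline()` inverts the geometric definitions: head-circle
points exactly on a circle (default radius 25 mm, a typical adult femoral
head); a symmetric neck of half-width 0.55 r about an axis at a configurable
angle (default 40° below the image x-axis, pointing infero-laterally); an
optional cam bump whose radial excess follows a smoothstep of angular width
20° and amplitude 0.15 r (≈3.75 mm, a pronounced but realistic cam), with
the tolerance crossing placed *analytically* at the requested departure
angle so ground-truth AA is exact by construction; an acetabular edge at the
requested centre-edge angle; and an acetabular articular polyline whose
single closest vertex sits exactly `joint_space_mm` from the femoral mJSW
polyline. Strictly concentric sparse arcs cannot realise an exact gap — the
chord sagitta at ~15° spacing undercuts it by ~0.3 mm — so the generator
pads the non-closest acetabular points outward by a sagitta bound and places
one designated vertex at the exact gap, making ground-truth mJSW exact.

The 85-point layout beyond the published ranges (15–28, 22–31, 78–84, edge
78) is the generator's own design, since the full anatomic template is not
public. Two layout choices serve measurement stability under noise: the
head-circle range spans a wide (192°) bump-free arc ending adjacent to the
departure scan region, limiting the leverage of landmark noise on the
extrapolated fitted circle, and junction landmarks concentrate around the
departure band, as anatomical templates concentrate points where the anatomy
is. Optional isotropic Gaussian noise (`landmark_noise_sd_mm`) is applied to
every landmark.

`generate_cohort()` draws, in causal order: sex (equal numbers), covariates
from sex-specific truncated normal distributions and an ethnicity
multinomial matching the reference cohort's descriptive statistics;
morphology from sex-specific prevalences (cam 15.4%/1.8% male/female,
pincer 8.9%/8.1%, dysplasia 5.6%/7.0%; pincer and dysplasia mutually
exclusive as LCEA classes); true angles conditional on morphology class;
per-site osteophyte presence from logistic models whose default log-odds
ratios echo the adjusted male effect sizes of the reference analysis (e.g.
cam→inferior femoral osteophyte OR 4.75), latent grades 1–3 given presence,
and gamma-distributed shaded areas per grade; JSN presence/grade likewise,
with the realising mJSW drawn around per-grade means plus a height slope
(0.012 mm/cm); and finally hip pain from a logistic model with a small
direct cam effect plus per-osteophyte effects. Because osteophytes sit
between morphology and pain, mediation-structured scenarios (cam → inferior
osteophyte → pain with no direct path) are a configuration away, which is
how the attenuation behaviour is tested. All effect sizes are simulator
configuration echoing published estimates — not ground truth re-derived
from any data.

What the generator does **not** emulate: pixel-level appearance, correlated
(non-iid) landmark placement error, osteophyte-deformed outlines
(osteophyte areas are attached as marks, not geometry), pelvic tilt or
rotation, right hips, and 3-D structure. Passing round-trip tests therefore
demonstrates internal consistency of measurement and generation, not
validity on real radiographs.

## Problem sizes in the tests

The test-suite simulations use sizes chosen to keep sampling error well
inside the asserted bands on a single CPU: 500 noisy hips for the
noise-robustness check; cohorts of 3,400–6,000 for parameter-recovery and
structural checks; 100,000 outcome-only rows (geometry skipped) for
convergence of empirical odds ratios to configured values within 5%; 200
replicates for the CI-coverage (n = 5,000 per replicate), global-null
type-I-error (n = 3,600, all suite cells) and mediation-attenuation
(n = 6,000, male stratum) simulations. The mediation scenario uses a common
(~18% baseline) and strongly painful (OR 5) mediator so that the indirect
path dominates sampling noise at that cohort size.

## Known limitations

* The neck-axis construction and height-adjustment rule are documented
  stand-ins for unpublished procedures; absolute AA values depend on the
  former.
* No pelvic-tilt correction is possible from a single-hip outline.
* The departure-point rule depends on the fitted circle's extrapolation;
  with heavy iid landmark noise the fitted-circle uncertainty at the
  junction is the dominant AA error source.
* Grading defaults are synthetic; real use requires ROC calibration against
  a graded subset.
* The association layer models binary outcomes only; ordinal grade models
  and formal mediation analysis are out of scope.
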