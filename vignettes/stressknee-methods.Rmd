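---
title: "Measuring anterior tibial translation in stress radiographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring anterior tibial translation in stress radiographs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`stressknee`, the assumptions behind them, the parameters that matter, and
the design decisions taken where more than one reasonable construction
exists. It states no empirical results beyond what the package's test
suite and acceptance script compute themselves.

## The measurement problem

Stress radiography provokes anterior tibial translation with a calibrated
15 daN posterior load and images the knee laterally before and after. The
quantity of interest is the forward (anterior) shift of the tibia relative
to the femur, in mm. Every construction in this package reduces to:

1. find a *femoral reference* (a point or a line attached to the femur),
2. find the *tibial axis*,
3. report the signed perpendicular distance between them
   (anterior-positive), and
4. subtract the unstressed from the stressed value.

Working with the *change* in position makes the measurement insensitive to
any reference-frame offset that is common to both views; working with
*signed* distances is necessary because the tibia can sit anterior or
posterior of the femoral reference, and a posterior-to-anterior crossing
must not be folded onto itself. An absolute-value variant is available
(`tibial_translation(..., absolute = TRUE)`) for comparison with
conventions that report magnitudes only.

## Segmentation

**Preprocessing.** Images are block-mean down-sampled (default factor 2)
and Gaussian-smoothed (default sigma 1.5 px at working resolution). The
down-sampling factor trades edge localization against cost; sub-pixel
refinement (below) recovers most of the lost precision. The mm coordinate
origin follows the resampled pixel centres so positions are comparable
across resolutions.

**Joint localization.** The joint space carries the least bone in the
beam, so the row-sum intensity profile dips there. We take the *global*
minimum within a configurable central band (default: the middle 60% of
rows). A profile can have several local dips (e.g. soft-tissue folds); the
deepest one corresponds to the largest bone-free gap, which on a centred
lateral knee view is the joint. A strictly monotone profile means no joint
is in the band, and is reported as an error rather than a guess.

**Edge paths.** Each bone contributes an anterior and a posterior edge,
modelled as a monotone path (one column per row) minimizing

`sum_r [ alpha * (1 - g_hat(r, c_r)) + beta * |c_r - c_{r-1}| ]`,
`|c_r - c_{r-1}| <= max_step`,

where `g_hat` is the across-edge gray-value gradient, normalized to the
search corridor, *signed* so that the posterior edge seeks a rising and
the anterior edge a falling transition along the anterior direction (bone
is brighter than soft tissue). Defaults `alpha = 1`, `beta = 0.25`/px,
`max_step = 3` px were chosen on phantoms as the weakest smoothing that
keeps paths straight through local noise; they are exposed in
`run_config()`. The search corridor (half-width 6 px) follows a row-by-row
tracking of the bright bone cross-section, which makes the path robust to
other gradients in the scene (the other bone, the stress-device rod). The
dynamic program is exact for the stated cost; the test suite checks it
against exhaustive path enumeration on small grids.

Integer-pixel paths quantize a near-vertical edge by up to half a pixel
*systematically* (the same rounding in every row), which would consume
most of a sub-millimetre error budget. Each edge point is therefore
refined by parabolic interpolation of the gradient magnitude around the
selected column — standard practice for locating smooth intensity edges —
bringing edge localization well below 0.1 px on clean data.

**Axes.** The shaft axis is the total-least-squares line (principal axis
of the scatter) through the per-row midpoints of the two edges, using rows
whose distance from the joint lies in the 8–14 cm band. Total least
squares is the right fit because errors live in both coordinates and the
line may be far from vertical. The same band is used for the tibia; the
band is measured as row distance from the joint, which for shaft tilts up
to ~40 degrees differs from arc length by under 25% and has no measurable
effect on the fitted direction for straight shafts. Both axis directions
are oriented *away* from the joint, which gives angles between axes an
unambiguous meaning. An image too short to cover the full band is an
error naming the available span, not a silently degraded fit.

**Flexion convention.** The flexion angle is reported clinically: a
straight leg measures 0 degrees. With away-oriented directions `u_f`,
`u_t` this is `180 - acos(u_f . u_t)` degrees; a description in terms of
"the angle between the away directions" alone would assign 180 degrees to
the straight leg, so the convention is fixed by the requirement that a
tibia rotated 40 degrees out of line measures 40.

**Condyle model.** The two femoral condyles are fitted with a
point-distribution model: training contours (32 landmarks in fixed
angular correspondence) are aligned by generalized Procrustes analysis
(translation, rotation, scale removed), the mean shape and the principal
modes retaining 95% of the variance are kept, and each landmark carries a
mean appearance profile (11 gray-value samples along its outward normal,
1 px apart). Fitting alternates appearance matching along the normals
(sub-pixel via parabolic interpolation of the SSD minimum), similarity
pose re-estimation, and projection onto the mode subspace with
coefficients clamped to ±3 standard deviations. Convergence: mean
landmark move below 0.1 px, at most 50 iterations.

Two practical choices matter here:

- *Side-specific appearance.* One shape family describes both condyles,
  but landmark `i` of the medial contour sees a different intensity
  context than landmark `i` of the lateral one (the other condyle's rim,
  the shaft). The default model is therefore a pair (medial + lateral)
  trained on the same synthetic family; with pooled appearance the two
  fits can collapse onto a compromise contour where the rims run close
  together.
- *Initialization from priors.* The fit starts from the condylar
  bright-mass centroid plus configurable offsets and radii
  (`condyle_offset_prior`, `condyle_radius_prior`). On phantoms these
  priors are the rendering family's nominal geometry; on clinical images
  they would come from configuration or annotation. This is a stated
  limitation, not a hidden assumption.

A fit that converges but does not straddle a real intensity edge (mean
inside-outside contrast below 8% of the image's robust intensity range,
e.g. in a blank region) is flagged as failed rather than trusted.

**Quality control.** The original workflow had a radiologist veto
inappropriate landmarks; here automated heuristics stand in: methods 1–3
require both axes, flexion within [0, 90] degrees, axes intersecting
within the image extended by 50%, and condyle contour areas within
[0.25, 4]x the model's mean area; method 4 additionally requires both
condyle fits converged. Flags are per method, and a translation is
reported only when both views pass for that method — failures partition
exactly, never silently.

## The four constructions

Methods 1 and 4 are *central* (reference from condyle interiors), methods
2 and 3 *tangent-based* (reference from posterior condyle margins).
Degenerate cases are resolved explicitly: when the femoral axis crosses a
condyle contour twice, method 1 takes the distal-most crossing (the
articulating margin); tangent-point ties break toward the smaller row
coordinate; a contour degenerate along the tangent direction is a
method-level failure. On pure-shift phantoms all four agree by
construction; under projectional condyle offset (the radiographic proxy
for limb rotation) the central references move less than the tangent
ones, which the test suite asserts as a direction-only inequality.

**Technical factors.** The tibial plateau line needed by the force-joint
metrics is nowhere defined by the measurement conventions themselves; we
construct it as the line through the most-proximal points of the tibial
anterior and posterior edge paths. This lands within ~2 mm distal of the
anatomical plateau on phantoms (the edge paths begin just below the
plateau corner) — a known, documented bias of the default strategy, which
is replaceable by passing an explicit plateau. Signs: force-joint distance
is positive with the skin point distal to the plateau; the force-joint
angle is positive when the load line points toward the plateau.

## The phantom generator

The phantom emulates exactly the features the pipeline consumes: a tilted
femoral shaft (default flexion 30 degrees — a typical stress position —
applied to the femur so the tibia stays vertical and an anterior shift
changes the axis distance by exactly the shift), two overlapping
near-circular condyles rendered *additively* (projection-like, so the
smaller condyle's rim stays visible inside the larger), a radiolucent
joint gap (6 mm), a vertical tibial shaft, and a bright thin rod for the
stress-device plunger, placed at the reference population's mean
force-joint geometry (39.7 mm distal, −10.58 degrees). Default raster:
640x420 px at 0.5 mm/px — the smallest canvas that holds the 8–14 cm
axis band on both sides of the joint. Noise is additive Gaussian on gray
levels; "moderate" in the tests means a standard deviation of 5% of the
bone-background contrast. Rendering is a pure function of (spec, seed).

What the phantom does *not* emulate: scatter and beam-hardening texture,
cortical/trabecular structure, overlapping fibula, patella, soft-tissue
gradients, metallic implants, and genuinely anatomical condyle shapes.
Passing the phantom batches therefore demonstrates the geometric
correctness and noise robustness of the chain, not clinical segmentation
performance; the published success rates on patient images (80–92%) are
not reproducible without those images, which is why the acceptance
criteria for the segmentation core are property-based.

## The cohort simulator

`cohort_params()` defaults encode the reference population: n = 177,
prevalence 129/177, per-method translation normals (torn vs intact), and
normal covariates at the published means/SDs. Values are drawn
untruncated; the intercondylar distance can therefore go slightly
negative where the population mean sits 1.25 SD above zero — a deliberate
simplification that keeps group moments exactly recoverable (truncation
would bias the means the recovery tests check).

The optional accuracy link draws a per-patient correct/incorrect flag
from a logistic model on the covariates, with the intercept chosen (when
not given) so the mean accuracy is ~0.729 at the covariate means. For
slope-recovery experiments the package generates one cohort per covariate
with only that covariate's slope active: fitting *univariate* models to
data generated from a multi-covariate logistic link would not recover the
generating slopes even with independent covariates (marginalizing a
logistic model over omitted covariates attenuates slopes —
non-collapsibility of the odds ratio), so the single-slope design is the
one for which univariate recovery is the correct expectation.

## Statistics conventions

- **ROC.** Empirical, no smoothing; positive call when score >= threshold
  (larger translation, more likely torn). The trapezoid AUC then equals
  the Mann–Whitney estimator, which the tests assert on tied data.
- **Youden cutoff.** Ties broken to the lowest threshold (maximizing
  sensitivity at equal J).
- **Wald intervals with a total-n denominator.** The published 2x2
  performance intervals for this system are Wald intervals whose standard
  error uses the *total* cohort size for every metric, not each metric's
  own denominator (reverse-engineering the printed intervals shows this
  unambiguously: with per-metric denominators the specificity interval of
  method 1 would be twice as wide as printed). `diag_performance()`
  defaults to that convention so the published tables reproduce exactly,
  and offers `ci_denominator = "metric"` for the statistically
  conventional per-metric version. Neither is clipped beyond [0, 1].
- **t-test.** Welch by default (no equal-variance assumption is
  defensible for clinical subgroups); pooled-variance available.
- **Logistic fits.** `stats::glm` IRLS (tolerance 1e-8, 25 iterations);
  Wald p-values and CIs; complete separation is an error naming the
  covariate, not a silently huge coefficient.
- **Fisher's exact test.** Two-sided by hypergeometric enumeration
  (`stats::fisher.test`), checked against a direct enumeration oracle.
- **AUC sample size.** Hanley–McNeil variance with the null variance
  taken at the null AUC, two-sided alpha, smallest integer n per group by
  direct search. Published sample sizes depend on unstated software
  choices, so this function documents its formula and is tested for
  monotonicity and divergence, not against any particular printed n.

## Problem sizes used in validation

The test suite validates translation recovery on 50 noise-free and 50
noisy phantom pairs with shifts spanning 0–15 mm (budgets: 0.5 mm for at
least 95% of noise-free cases per method, 1.5 mm for at least 90% under
moderate noise); binormal AUC simulations use 200 replicates of the
177-patient configuration; logistic slope recovery uses cohorts of 10^5
patients, three replicates per covariate. These sizes make the checks
sharp at interactive runtimes; all are parameters, not constants.

## Known limitations

- Metallic implants, severe osteoarthritis and other strong departures
  from the two-bones-plus-condyles scene model are out of scope; the edge
  tracker assumes a single dominant bright cross-section per bone.
- DICOM input is not read directly; images arrive as PNG/TIFF with a YAML
  sidecar carrying the pixel spacing (measurements are meaningless
  without a true mm scale, so images without spacing are rejected).
- Condyle-fit initialization relies on geometric priors (see above).
- The plateau construction biases the force-joint distance slightly
  distal; replace it where a sharper plateau definition is available.
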