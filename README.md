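# stressknee

Automated measurement of **anterior tibial translation** in lateral knee
stress radiography, and evaluation of its diagnostic performance for
complete **anterior cruciate ligament (ACL) tear**.

A torn ACL lets the tibia slide forward relative to the femur. Stress
radiography quantifies this: a lateral knee X-ray is taken before and after
a calibrated posterior load (15 daN) is applied, and the forward shift of
the tibia between the two views is measured in mm. Manual measurement is
reader-dependent; this package implements a computer-assisted pipeline that
segments the bones, constructs femoral reference landmarks, and measures
the translation by four geometric methods, together with the statistics
layer used to judge them.

## What the pipeline computes

For each view:

- **Joint localization** — the joint space is the row minimizing the
  row-wise sum of gray values (least bone in the beam).
- **Bone edges** — anterior and posterior edges of femur and tibia as
  minimal-cost monotone paths: `cost(r, c) = α·(1 − ĝ(r, c)) + β·|Δc|`,
  where `ĝ` is the normalized gray-value gradient oriented across the edge
  and `β` penalizes column jumps (dynamic programming, sub-pixel refined).
- **Shaft axes** — total-least-squares midline of the two edges, fitted
  8–14 cm from the joint space.
- **Femoral condyles** — a point-distribution (Procrustes + PCA) shape
  model with per-landmark appearance profiles, fitted by an iterative
  active-shape search with mode coefficients clamped to ±3√λ.

The **tibial position** TP is the signed (anterior-positive) distance
between a femoral reference and the tibial axis TA; the **translation** is
`TP(stressed) − TP(unstressed)`. The four references are:

| method | femoral reference |
|---|---|
| 1 | midpoint of the femoral-axis ∩ condyle-margin intersections |
| 2 | midline of the two posterior condyle tangents parallel to TA |
| 3 | midpoint of the tangent points of posterior tangents parallel to FA |
| 4 | midpoint of the two condyle-model centres |

Technical factors measured per examination: flexion angle (between the
axes), intercondylar distance (between condyle centres), and the signed
force-joint distance/angle of the stress-device load line relative to the
tibial plateau.

The diagnostics layer provides empirical ROC curves with trapezoid AUC
(= Mann–Whitney estimator), Youden-optimal cutoffs (max `J = sens + spec −
1`), 2×2 diagnostic performance with Wald 95% CIs, univariate logistic
odds ratios (`OR = e^β`), Welch t / Fisher exact group comparisons, and a
Hanley–McNeil AUC sample-size calculation.

Because clinical stress radiographs are rarely shareable, the package
includes a **phantom generator** (radiograph-like image pairs with exact
geometric ground truth) and a **cohort simulator** (per-patient
measurement tables with specified group distributions), so every stage is
testable end to end.

## Worked example

```r
library(stressknee)

# a phantom pair with a known 10 mm anterior shift of the tibia
spec <- phantom_spec(tibial_translation_mm = 10, seed = 7)
pair <- render_phantom_pair(spec)
rec  <- measure_knee_pair(pair$pre, pair$post, id = "phantom-10mm")
print(rec)
#> <patient_record> phantom-10mm
#>   method 1: +9.99 mm
#>   method 2: +9.99 mm
#>   method 3: +9.99 mm
#>   method 4: +10.00 mm
#>   flexion 30.0 deg, intercondylar 3.88 mm, force-joint 37.2 mm / -10.6 deg

# a simulated 177-patient cohort evaluated like a clinical study
cohort <- generate_cohort(cohort_params(seed = 1))
ev <- evaluate_methods(cohort)
print(ev)
#> <method_evaluation> 177 patients (0 dropped for any failed method)
#>   method 1: AUC 0.712, cutoff 9.65 mm, sens 56.1%, spec 84.4%, acc 63.3%
#>   method 2: AUC 0.655, cutoff 10.03 mm, sens 52.3%, spec 82.2%, acc 59.9%
#>   method 3: AUC 0.748, cutoff 9.15 mm, sens 43.2%, spec 100.0%, acc 57.6%
#>   method 4: AUC 0.745, cutoff 10.54 mm, sens 45.5%, spec 100.0%, acc 59.3%
```

All four methods recover the applied 10 mm shift to within 0.01 mm on the
noise-free phantom. In the simulated cohort the AUCs scatter around their
population values (≈0.73–0.77 for these group distributions); single-cohort
cutoffs and accuracies vary from draw to draw, as they do across clinical
cohorts of this size.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","stressknee.R",package="stressknee"))')" \
    simulate --n 177 --seed 1 --out cohort.csv
```

with subcommands `phantom`, `simulate`, `measure`, `evaluate` (exit codes:
0 ok, 2 input error, 3 segmentation failure, 4 statistics error).

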