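---
title: "Sagittal-plane TKA planning: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sagittal-plane TKA planning: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagplan)
```

## The problem

In conventional total knee arthroplasty the sagittal orientation of the
femoral component is set by an intramedullary (IM) rod whose entry point is
traditionally placed 5-10 mm anterior to the intercondylar notch roof, and the
tibial cut by an extramedullary (EM) jig aligned along the front of the leg.
Both choices are sensitive to patient-specific sagittal bowing and soft
tissue: a rod entering at a fixed point in a bowed femur can seat the
component in extension and risk notching the anterior cortex, and an EM jig
referenced by palpating the fibula is unreliable in obese patients.

`sagplan` implements a lateral-radiograph planning scheme as executable
geometry. For the femur, the IM guide line is drawn at the implant's anterior
flange angle in flexion relative to the anterior cortex line and made tangent
to the posterior wall of the medullary canal; its intersection with the
intercondylar groove gives the femur entry distance (FED) once half the rod
diameter is added. For the tibia, the EM guide line is the fibular shaft axis
(FSA) rotated by a planning slope angle (PSA), and two anterior offset
distances (at 7 cm below the tuberosity and at the ankle) transfer the plan to
the operating field. Planned and achieved resections are both scored against a
cortical-midline reference axis: the gamma angle (femur, positive = flexion)
and the delta angle (tibia, positive = more posterior slope), with a target of
staying within 2 degrees of the plan.

## Coordinate frame and sign conventions

All geometry lives in one sagittal frame: x anterior (+) / posterior (-),
y proximal (+) / distal (-), units mm. `signed_angle()` is positive for
counter-clockwise rotations in this frame and folds to (-90, 90], with the
boundary reported as +90. Consequences, all derivable from the frame:

* **Flexion of a femoral guide line is positive (CCW)**: the proximal end of
  the line tips posteriorly, following the bowed canal, and the rod entry
  point moves anteriorly. `signed_angle(line_a, line_b)` equals the anterior
  flange angle by construction.
* **Posterior slope of a tibial guide line is positive (CCW)**:
  `signed_angle(fsa, em_line)` equals the PSA.
* **Bowing is positive when anterior** for both bones. Because the femoral
  measurement windows run proximally from the knee and the tibial windows run
  distally from it, the proximally-oriented window midlines rotate in opposite
  senses for the same anterior bow; `measure_dfb()` and `measure_ptb()` each
  apply the orientation that makes "positive = anterior bowing" hold.

Geometric predicates use an absolute tolerance of 1e-9 mm; all angle work is
done in radians internally and reported in degrees.

## The synthetic bone model

The generator stands in for annotated radiographs. Each shaft is
piecewise-linear with a single bowing hinge 90 mm from the distal reference
landmark (the posterior Blumensaat point for the femur, the tuberosity for the
tibia). Ninety millimetres is the midpoint between the 4-7 cm and 11-14 cm
bowing measurement windows, so the window-midline construction recovers the
generating bowing angle identically -- the bowing parameter is exactly
identifiable, which is what makes the 0.1-degree round-trip contract testable.
Outer cortices, canal walls and the anterior skin are parallel offsets of the
midline; a distal (femur) or proximal (tibia) metaphyseal flare and a small
condylar block carry the articular landmarks. The tibial plateau line is
tilted by the native slope relative to the perpendicular of the *same* 7/11 cm
cortical-midline axis that `measure_tps()` uses, again making the parameter
identifiable by construction.

Defaults (all configurable): femoral shaft coverage 230 mm with a 28 mm outer
and 13 mm diaphyseal canal diameter; tibial coverage 300 mm with a 24 mm outer
diameter; fibular axis 12 mm posterior to the posterior cortex and parallel to
the proximal shaft axis; condylar proportions typical of a lateral knee
radiograph. Only the bowing/slope/soft-tissue means and SDs are cohort
quantities (DFB 4.4 +/- 1.7 deg, PTB 2.0 +/- 1.5 deg, TPS 8.2 +/- 4.3 deg,
TST 8.8 +/- 3.8 mm); every other proportion is a stand-in and is not claimed
to be cohort-derived. Cohort sampling truncates the normals at +/-3 SD and at
physiologic floors (TST >= 1 mm) to avoid degenerate anatomy.

What the generator deliberately does not emulate: pixel noise and observer
variability of real radiographs, osteophytes, cortical-thickness variation,
non-uniform bowing (a real diaphysis curves continuously), out-of-plane
rotation of the limb during acquisition, and any coronal-plane information
(the HKA angle is carried as a covariate scalar, never computed). Passing
round-trip and zero-noise tests therefore demonstrates internal consistency of
the constructions, not measurement accuracy on clinical images.

## Femoral construction details

* **Line A** is a total-least-squares fit to anterior-cortex samples over a
  40-140 mm window. The window is measured as arc length along the anterior
  cortex starting at the Blumensaat level (the perpendicular chord from the
  posterior Blumensaat point), which keeps the trochlear front and the
  metaphyseal flare out of the fit; the span matches the other shaft
  constructions and is configurable.
* **Line B** is Line A rotated by the flange angle and re-anchored as the
  supporting tangent of the posterior canal wall, restricted to the distal
  350 mm of the canal (a finite rod cannot engage more canal than its
  length). Tangency is an exact support-line computation, verified in the
  tests against exhaustive vertex search.
* **FED** uses the Euclidean distance from the Line B/groove intersection to
  the notch roof. The alternative (arc length along the groove) was rejected
  because the planning figure shows a straight caliper-style measurement; this
  is a package decision, not an authors' statement.
* **Line C** joins the cortical-diameter midpoints at 7 and 11 cm of
  posterior-cortex arc length. Arc length (a ruler run along the cortex) was
  chosen over straight-line offsets for all "N cm from the landmark"
  constructions; the two differ only at the third decimal for realistic
  bowing, and the choice is applied uniformly.

## Tibial construction details

The PSA was a surgeon's choice in the validation cohort (baseline 0 degrees to
the FSA, more when the native slope was large; observed range -1 to 4). No
formula was reported, so the package treats PSA as an explicit input and also
offers an auditable `slope_adaptive` policy
(`gain * max(0, native_tps - threshold)`, clamped to the observed range) for
simulation work; the cohort default adds 0.5 deg per degree of native slope
above 10 deg. The 7 cm offset point lies on the anterior cortex (the skin
alternative differs by TST and is available through the skin contour); the
ankle point is a supplied landmark, not detected. Offset distances are
perpendicular distances to the guide line, so the guide's anchor position
cancels in `offset_c - offset_b` and in the delta angle -- a tested property
that is what makes the transfer value usable intraoperatively.

## Execution, correction and notching

Execution error is a pure rotation of each resection orientation about its
distal reference (the femoral entry point; the tibial guide anchor), sampled
from a configurable normal or 3-SD-truncated normal. Translation and
cut-thickness errors are out of scope. The default demonstration model
(femoral bias +1.2 deg towards flexion, SD 1.8; tibial bias 0, SD 0.9) is a
package calibration chosen to produce cohort-scale scatter -- the validation
study reports outcomes, not an error model -- and should be replaced when a
system-specific estimate is available.

Implants whose tibial stem is tilted 3 degrees (J2BCS, Exult) are cut with
their provided 3-degree slope guide so the stem clears the posterior cortex,
implementing 3 degrees more posterior slope than planned; the validation
arithmetic subtracts this extra before scoring, while neutral-stem systems
(Physica, U2) are scored directly. The target interval is closed at +/-2
degrees: a case exactly at the boundary counts as within target, since the
study states the range inclusively.

Notching is flagged when the anterior flange cut, anchored where the distal
resection exits the anterior cortex and directed at the flange angle in
extension from the achieved IM axis, ends posterior to the anterior cortex at
its proximal exit level -- i.e. the cut has undermined the cortex. Exact
execution of the tangency-constructed plan makes the cut parallel to the
fitted cortex line and never notches, across the whole documented anatomy
range. Under rotation-only errors the flag trips only for large flexion-side
malrotation (the trochlear prominence shields the cortex otherwise); the
clinically discussed extension-with-fixed-entry mechanism involves
anteroposterior translation and sizing, which this error model excludes by
design.

## Statistical harness

* `paired_compare()` screens the paired differences with a Kolmogorov-Smirnov
  test against the normal (alpha 0.05) and then runs a paired t test or the
  Wilcoxon signed-rank test. The study protocol names the "rank-sum" test for
  its paired comparisons; the signed-rank test is the coherent paired
  analogue, and the package implements that under an explicit label rather
  than mislabelling the computation. Constant differences make the comparison
  degenerate: the package returns `NA` with `test = "degenerate"` instead of a
  manufactured p-value.
* `regress_abs_differences()` fits OLS of the absolute pre/post angle
  difference on the study's predictor sets (sex, age, BMI, DXA T-score, HKA,
  plus DFB for the femur or TPS/TST/PTB for the tibia), reporting B, SE,
  standardised Beta (consistent with a z-scored refit), t, p and 95% CI.
  An ill-conditioned design (condition number above 1e8) raises a warning
  rather than silently dropping terms. Bilateral knees are treated as
  independent cases -- no patient-level clustering -- matching the reported
  analysis; signed differences are available but off by default.
* `sample_size_paired_t()` searches the noncentral-t power function for the
  smallest n; the design values (effect 0.4, alpha 0.05, power 0.95) give 84,
  and a 25% dropout inflation gives 112. Tests cross-check the search against
  `stats::power.t.test` and a direct 10^4-replicate simulation.

## Problem sizes and numerical choices in the validation suite

The shipped suite runs a 500-case zero-noise cohort (expecting 100% within
target and mean differences at machine precision), a 100-anatomy
generator/measurement round-trip sweep at 0.1 deg / 0.1 mm, brute-force oracle
comparisons on 10^4-vertex contours, and 2000-replicate null calibrations of
the paired test (type-I error) and the regression (type-I error and CI
coverage), all under fixed seeds. These sizes are the package's choice of a
demonstration scale; the constructions themselves are closed-form and run in
milliseconds per case.

## Known limitations

The model is strictly 2D: coronal alignment, rotational alignment and the
intraoperative Whiteside-line placement of the entry point are out of scope.
The single-hinge bone is an idealisation chosen for identifiability, not a
morphometric claim. Radiographic measurement noise is not separated from
execution error, and the notching flag inherits the rotation-only error
model's blind spot for translational mechanisms. Reproducing the validation
study's headline accuracies (80.6% femur, 95.7% tibia) requires its 93
patients' radiographs, which are not available; the package's cohort runs are
property checks and demonstrations, not a re-estimate of those figures.
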