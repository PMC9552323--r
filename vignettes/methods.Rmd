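---
title: "Methods: simulating adaptive and conventional dose-painted prostate radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating adaptive and conventional dose-painted prostate radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpaintsim)
```

## What the package simulates

`dpaintsim` is a desk-scale treatment-simulation pipeline for hypofractionated
(7-fraction) prostate radiotherapy. It compares four study arms crossing two
prescription strategies with two delivery workflows:

* **Homo-conv / Homo-adap** — homogeneous prescription doses
  (43.89–60.89 Gy ladder) planned to a PTV, with rectum dose-volume
  *objectives*;
* **DPBN-conv / DPBN-adap** — dose painting by numbers: voxel-wise
  TCP maximization driven by an ADC map, under hard rectum dose-volume
  *constraints* ("treat-to-tolerance", no upper limit on prostate voxel
  dose).

Conventional arms plan once on a reference anatomy and deliver each fraction
after a rigid CTV-centroid alignment (emulating gold-marker registration);
rotations and deformations of the anatomy are not compensated. Adaptive arms
re-plan daily on the anatomy-of-the-day with smaller margins/robustness
settings. Accumulated 7-fraction dose (EQD2 for TCP, physical for DVH
metrics) is evaluated on the reference frame after deformable dose mapping
along known ground-truth displacement fields.

Because no patient images ship with the package, a seeded synthetic-anatomy
module stands in for the MR-linac image sets and patient ADC maps. Every
quantity in the pipeline is therefore computable from a configuration and a
seed alone.

## The tumor control model

TCP is a product over prostate-CTV and seminal-vesicle voxels of voxel
control probabilities

$$ \mathrm{TCP} = \prod_i \Big[\textstyle\sum_g P(g \mid \mathrm{ADC}_i)\,
   S_g(E_i)\Big]^{v_i / v_\mathrm{ref}}, $$

where $E_i$ is the accumulated EQD2 of voxel $i$
($E = D\,(d + \alpha/\beta)/(2 + \alpha/\beta)$, $d = D/N$,
$\alpha/\beta = 1.93$ Gy), $P(g \mid \mathrm{ADC})$ an ordinal-logistic
('low precision') posterior over Gleason categories GS6–GS9 with cutpoints
(900, 750, 600)·10⁻⁶ mm²/s and width 80, and $S_g$ a logistic control curve
in EQD2 with $D_{50}$ = (48, 60, 70, 80) Gy and $\gamma_{50} = 2.5$ per
category. Seminal-vesicle voxels have no ADC and are assigned a degenerate
GS6 (lowest-risk) posterior.

Three modelling choices deserve comment:

* **Mixture before exponent.** The voxel is treated as a single lesion of
  uncertain grade: the posterior mixes the category survival curves first
  and the volume exponent $v_i/v_\mathrm{ref}$ (voxel volume over the 1 cm³
  reference volume at which the curves are calibrated) is applied to the
  mixture. This makes uniform-dose TCP independent of voxelization at fixed
  total volume.
* **Calibration.** The shipped curve parameters are the package's own
  calibration, constrained by the clinical anchors the pipeline must
  reproduce: the 43.89 Gy/7 fx prescription corresponds to 91.6 Gy EQD2 at
  $\alpha/\beta = 1.93$; a pure-GS6 seminal-vesicle volume at that EQD2 has
  control probability above 99%; prescription doses of 44–61 Gy put
  GS6-dominated targets in the high-90s TCP regime; and the dose-response
  flattens at the upper end of that range (diminishing marginal returns,
  which is why painted and homogeneous plans converge in TCP at high dose).
  The calibration is versioned as YAML
  (`inst/extdata/calibration_default.yaml`) and can be replaced wholesale.
* **Monotone ADC→grade mapping.** Low ADC (cellular, radioresistant tissue)
  implies high probability of high Gleason categories; expected grade is
  non-increasing in ADC by construction.

## Margins and uncertainty budgets

Both workflows carry three 1 mm-SD uncertainty components (intrafraction
motion, interobserver delineation, machine precision); the conventional
workflow adds the interfraction-deformation residual and
registration/table-translation components (1 mm SD each). Margins follow the
van Herk recipe with effective components for a finite fraction number $N$:

$$ M = 2.5\,\Sigma_\mathrm{eff} + 0.7\,\sigma_\mathrm{eff}, \qquad
   \Sigma_\mathrm{eff}^2 = \Sigma^2 + \sigma^2/N, \quad
   \sigma_\mathrm{eff}^2 = \sigma^2 (1 - 1/N). $$

The systematic/random split of the components is not uniquely determined by
their list alone. The package defaults to the only physically coherent split
that reproduces both printed margins under ceiling rounding: in the adaptive
workflow all three components act per-fraction (daily redelineation turns
the delineation error into an execution error), giving a raw margin of
2.76 mm → **3 mm**; in the conventional workflow delineation, deformation
residual and registration/table are systematic ($\Sigma = \sqrt3$) while
intrafraction and machine are random ($\sigma = \sqrt2$), giving 5.45 mm →
**6 mm**. Both the split and the rounding policy are configuration entries,
and the split is flagged as reverse-engineered in the documentation.

The same budgets drive the sampled execution errors at delivery time:
systematic components are drawn once per course, random components per
fraction. Because the synthetic fraction anatomies already realize the
interfraction deformation explicitly, the deformation-residual component is
excluded from the sampled delivery errors (it would be counted twice);
margins, however, are computed from the full budgets.

## Synthetic anatomy and deformations

The phantom is a 44×44×36 grid at 3 mm isotropic spacing (the dose-grid
resolution; axes LR/AP/SI, masks are voxel-centre inclusions of analytic
shapes): an ellipsoidal prostate (volume sampled in 30–60 cm³), two
seminal-vesicle lobes superior-posterior (~10 cm³ total), a tubular rectum
(radius 11–14 mm) posterior to the prostate with a 4 mm gap, and an
ellipsoidal bladder (~90 cm³) superior-anterior. OAR masks are cropped
against the targets. Only topology and adjacency matter for the mechanisms
studied, which is why simple parametric shapes suffice.

ADC maps are Gaussian random fields (mean 1100, SD 140 ×10⁻⁶ mm²/s within
the prostate, 12 mm correlation length) multiplied by 1–3 focal suppression
profiles (radius 4–9 mm, 40% depth) emulating high-grade lesions; the
resulting prostate means land near the ~1050·10⁻⁶ mm²/s scale typical of
clinical reports.

Interfraction variation composes three diffeomorphisms
(reference → fraction): a radial rectum inflation/deflation (volume ratio
log-normal, SD 0.2, clipped to [0.5, 2.2] — the upper end reproduces the
rectum-doubling behaviour that breaks volume-at-dose bookkeeping), a
Gaussian-filtered random vector field (2 mm SD per axis, 25 mm correlation
length), and a rigid shift (SD 1.5/2.5/2.5 mm LR/AP/SI) plus rotation about
the LR axis (SD 1.5°). These magnitudes are plausible stand-ins chosen once
as study conditions — interfraction prostate translations of 2–3 mm,
rotations dominated by the LR axis, and smooth deformations of a few mm are
the clinically reported scales — and are exposed in the configuration
rather than asserted as measured values. Fraction masks are exact
voxelizations of the deformed analytic shapes via the numerically inverted
transform (fixed-point iteration for the smooth part, analytic inversion
for the rigid and radial parts). Both DVF directions are stored: the
fraction-grid field pulls reference data (the ADC map) into the fraction
frame, the reference-grid field pulls fraction data (dose) back. Fields
with non-positive Jacobian determinant are rejected and regenerated (or
raise an error, per configuration). Self-consistency — warping the fraction
prostate back along the stored DVF — reproduces the reference mask with
Dice ≥ 0.95 on all generated fractions.

The reference ADC is transferred to each fraction by pull-back trilinear
interpolation (nearest-neighbour fallback at the prostate edge), assuming
pre-treatment ADC invariantly determines radiosensitivity over the course;
under default deformation amplitudes the transferred distributions preserve
the mean within 5% and the SD within 10%.

## Dose engine

Dose is linear in the weights of a fixed beamlet basis: 7 equispaced
coplanar beams, each a 6 mm lattice of Gaussian pencil beamlets (lateral
penumbra SD 4 mm, so the 90→10% falloff spans about 1 cm, a realistic MV
gradient) with exponential depth attenuation (0.004 mm⁻¹) referenced to the
grid entry plane. This continuous-intensity basis is deliberately more
flexible than a deliverable segmented MLC plan — conservative for TCP
comparisons, since both arms share the flexibility. There are no
heterogeneity, magnetic-field or couch-attenuation effects, so the
influence matrix is anatomy-independent and is built once per case and
shared by all arms, fractions and scenarios; delivery translations become
exact index shifts on the dose grid.

## Plan optimization

Both arms optimize non-negative beamlet weights with L-BFGS-B and analytic
gradients. Dose-volume quantities use smooth sigmoid surrogates (0.6 Gy
width) during iteration and are verified by exact voxel counting afterwards;
hard constraints are enforced by penalty escalation until the exact check
passes (0.1 pp tolerance), otherwise the optimization reports infeasibility
naming the binding constraint.

* **Homogeneous:** least-squares uniformity at $D_p$ on the PTV with
  one-sided guards just inside the D98 > 0.95 $D_p$ / D2 < 1.05 $D_p$ band
  (hard, re-checked exactly), SV-PTV near-minimum 43.89 Gy, rectum V33/V38/V41
  objectives, soft D2 < 42.7 Gy for rectum and bladder, and a
  distance-decaying dose-falloff objective outside the targets. Plans are
  ADC-independent and reusable across the ADC variants of an anatomy.
* **DPBN:** maximizes a smooth minimum of log-TCP over the robustness
  scenario set (nominal plus ±robustness-distance displacements along each
  axis — 3 mm adaptive, 6 mm conventional, only the TCP objective is
  robust), subject to hard nominal rectum constraints, SV near-minimum, the
  same soft D2 and falloff objectives, and no upper bound on prostate voxel
  dose. With the shipped falloff weights the optimizer typically saturates
  in the flat TCP region before the rectum constraints bind (the
  treat-to-tolerance aim then leaves all three metrics strictly inside
  tolerance); the constraints become active for rectum-adjacent geometries.

Stopping: 150 L-BFGS-B iterations per penalty round (60 when warm-started
from the previous day's plan in adaptive courses), relative tolerance 1e-9
via `factr`. Initialization is deterministic (uniform weights scaled to the
target level), so plans are reproducible bit-for-bit from (config, seed).

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere; binary masks are warped by
  interpolating the 0/1 field and thresholding at 0.5; ADC uses
  nearest-neighbour fallback at mask edges to avoid rim artefacts.
* FFT-based Gaussian smoothing and ellipsoidal dilation assume periodic
  boundaries; all structures keep ≥ 15 mm clearance from the grid edge, so
  wrap-around cannot reach them.
* Margins below half a voxel round to zero with a warning; empty-vs-empty
  Dice is defined as 1 with a warning; Hausdorff on an empty mask, empty
  targets, zero fractions and negative doses raise errors.
* D$_{x\%}$ uses type-7 quantile interpolation on the sorted voxel doses;
  volume-at-dose is a strict-inequality voxel count.
* Scenario displacements are rounded to integer voxels (3 mm), making the
  robust evaluation exact rather than interpolated.

## What the generator does and does not emulate

The synthetic module reproduces the *mechanisms* the pipeline studies:
focal low-ADC targets for painting, interfraction rigid/deformable motion
with known ground truth, rectum volume changes up to ~2× that corrupt
volume-at-dose bookkeeping under mapping and recalculation, and target
misses when rotations/deformations exceed the conventional margin. It does
not emulate MRI physics (bias fields, distortion, noise spectra),
intra-fraction motion traces, bone/tissue heterogeneity, or inter-patient
anatomical diversity beyond the sampled shape parameters. Passing tests
therefore certify the pipeline's internal consistency and the model's
mechanism-level behaviour, not clinical performance on real patients.
Similarly, because the ground-truth DVF is known, registration error enters
only through the optional perturbed-DVF surrogate; real
deformable-registration error would add a bias the similarity report can
only bound, not remove.

## Problem sizes

The shipped configuration runs every study quantity at desk scale: 69 696
voxels, ~1 300 beamlets, full 7-fraction courses in seconds per plan. The
cohort analyses use 5 cases (both DPBN workflows, ~3 minutes total) for the
accumulated-TCP regime and the first 3 of those cases (21 daily adaptive
plans) for the treat-to-tolerance check; the engineered target-miss
experiment uses one case and one fraction. These sizes were chosen so the
entire analysis reruns comfortably on a single CPU while keeping every
cohort property comfortably away from its acceptance threshold.

## Known limitations

* The dose engine's conformity is controlled by penalty weights, not by
  deliverability; absolute OAR doses should be read as relative comparisons
  between arms, not as clinical predictions.
* The dose-response calibration is anchored, not fitted to outcome data;
  TCP values are meaningful for arm *comparisons* under the stated model
  only.
* Rectum metrics use relative volumes of the full organ cross-section (as
  clinical criteria do), not wall doses; the volume-change analyses exist
  precisely to show the resulting bookkeeping fragility.
* Residual execution errors are rigid; systematic delineation error is
  sampled as a displacement, not a contour bias.
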