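---
title: "Evaluating corrected cone-beam CT for breast dose calculation: methods and design"
author: "cbctdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating corrected cone-beam CT for breast dose calculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cone-beam CT (CBCT) is acquired at the treatment couch to verify patient
position. When a breast patient's anatomy changes — swelling or shrinkage
of the breast beyond about 5 mm — the clinical question is whether the
original plan still delivers an acceptable dose, which today is answered
with an extra repeat CT (rCT). If the CBCT itself supported accurate dose
calculation, many repeat CTs could be avoided. Raw CBCT cannot be used
directly: scatter distorts the Hounsfield-unit (HU) scale, low-frequency
shading corrupts large image regions, and the reconstructed field of view
(FOV) is a limited cylinder.

`cbctdose` implements the full evaluation chain for three CBCT correction
strategies — multilevel-threshold density override (`CBCT_HU`), iterative
analytical grey-level conversion plus shading correction (`CBCT_CC`), and
a virtual CT assembled from the deformed planning CT (`CT_V`) — on
synthetic cases whose ground truth is known exactly, so the accuracy of
every stage is measurable rather than assumed.

## The synthetic cases

No public image data accompanies this problem, so `generatePhantomCase()`
builds each case from scratch:

* **Anatomy.** A thorax phantom: elliptic-cylinder body (soft tissue,
  40 HU) with an 8 mm subcutaneous adipose shell (-90 HU), two lungs
  (-750 HU), a heart (soft tissue), a bony spine and ribs (700 HU), and a
  spherical breast bulge (glandular, 20 HU) on the anterior chest wall.
  The default grid is 128 x 128 x 64 voxels at 2.5 mm spacing, which
  keeps an end-to-end case under a minute while leaving organs many
  voxels across. The structure set (BODY, whole-breast CTV, boost CTV,
  heart, lungs) is generated analytically; CTVs are contracted to stay
  5 mm inside the BODY surface, mirroring clinical contouring practice.
* **Deformation.** The anatomical change of interest is a smooth
  radial displacement of the breast surface (Gaussian bump about the
  breast apex, sigma 25 mm), applied as a pull-back field. The stored
  amplitude is calibrated analytically so the *tracked surface* moves by
  the requested peak (default 8 mm; the inclusion criterion is > 5 mm).
  The field's Jacobian determinant is checked to be positive everywhere;
  a folding field is rejected.
* **Two acquisitions.** The planning CT and repeat CT share the
  underlying anatomy but receive independent Gaussian noise draws
  (sigma 8 HU each), as two scans of one patient would. This matters: it
  keeps the virtual CT from being bit-identical to the repeat CT by
  construction.
* **CBCT artifacts.** Inside a cylindrical FOV (radius 115 mm, length
  120 mm, centred between body and breast so the whole breast is
  visible), the CBCT is the repeat-CT anatomy through an affine HU
  distortion (gain 0.9, offset -30 HU), plus a smooth in-plane shading
  field (cosine modes band-limited at a 100 mm scale, normalised to an
  80 HU maximum inside the FOV), plus Gaussian noise (sigma 20 HU).
  Outside the FOV the volume is air. Artifacts are modelled
  phenomenologically — these are exactly the corruption classes the
  correction methods address — rather than by scatter physics, so the
  injected ground truth (distortion parameters, shading field,
  deformation field) is returned with every case and downstream accuracy
  is measurable exactly.

What the generator does **not** emulate: projection-domain reconstruction
artifacts (streaks, motion, beam hardening), realistic scatter spatial
structure, anatomical texture inside organs, and couch/posture
differences beyond the breast deformation. Passing tests therefore show
that the pipeline recovers the *modelled* corruption classes with the
stated accuracy; they do not certify clinical CBCT correction quality.

## The correction methods

**Density override (`correctHuOverride`).** Exact multilevel Otsu
(dynamic programming on a 1-HU-resolution histogram) places five
thresholds that partition the grey levels inside BODY-and-FOV into six
ordered classes, which receive fixed mass densities (air 0.00121, lung
0.26, adipose 0.95, tissue 1.05, cartilage/bone 1.6, other 3 g/cm^3).
The raw grey levels are kept unaltered alongside; HU accuracy metrics for
this method are computed on the raw grey levels, which is why its MAE is
large by construction. Ties at a threshold go to the lower class. The
histogram is restricted to BODY intersected with the FOV so the air
padding outside the FOV cannot dominate the air class.

**Analytical conversion and correction (`correctAnalytical`).** Two parts
per iteration (default 3 iterations): (1) a conversion function from CBCT
grey levels to CT HU, estimated from the joint histogram of the CBCT and
the deformably aligned planning CT — 64 x 64 bins over each image's
1st-99th percentile range, the modal CT bin of every sufficiently
populated CBCT column (at least 0.1 % of the masked voxels) taken as a
tissue pair, monotonised by pool-adjacent-violators, evaluated by linear
interpolation with clamped ends; (2) a shading correction: the difference
map (deformed CT minus converted CBCT) restricted to the FOV, Gaussian
low-pass filtered (25 mm FWHM), added back. The conversion support is the
whole FOV rather than the body only — the air column then anchors the low
end of the mapping, which prevents the out-of-range clamp from injecting
a spurious low-frequency error at the body boundary (we observed exactly
this failure mode with a body-only support). Iterations that increase the
masked MAE against the deformed CT are rejected and the best image is
kept. A useful side effect of the modal-column mapping is that it acts as
a soft quantiser toward tissue plateau values, suppressing part of the
CBCT noise.

**Virtual CT (`buildVirtualCt`).** The planning CT is warped onto the
CBCT anatomy; wherever an air pocket (connected component below -300 HU
inside BODY, at least 0.5 cm^3) is present in either the warped CT or the
converted CBCT, values are replaced from the converted CBCT. Outside the
replacement set the virtual CT equals the warped planning CT bit-exactly.
Note that with a -300 HU threshold the lungs legitimately qualify as
"air" regions in a thorax phantom and are replaced as well; this is a
consequence of the published threshold choice, and it is why the virtual
CT's lung HU carries converted-CBCT noise.

**Registration.** Rigid alignment is a multi-resolution Nelder-Mead
search over 6 degrees of freedom (a `rot3` mode restricts it to the three
rotations) on the mean-squared HU difference; the metric ignores a 15 mm
rind at the grid boundary so out-of-extent fill cannot bias the optimum,
and the result is never worse than the identity. Deformable registration
is Thirion-style demons (3 levels, 50 iterations per level, Gaussian
field regularisation of sigma 2 voxels, per-step displacement capped at
one voxel) with an early stop that keeps the best field if the MSE rises
three iterations in a row. Every pipeline stage accepts an injected
ground-truth transform or field, and the cohort analyses run with the
ground truth injected, so correction accuracy is reported with
registration error excluded; the registration quality itself is tested
separately.

## The dose chain

The planning technique is a partial-VMAT breast arrangement:
70 % of the dose from two tangential conformal fields (gantry 55/235
degrees for a left-sided case) and 30 % from four short VMAT arcs (spans
of 40-80 degrees, discretised every 5 degrees). Apertures are rectangles
fitted to the CTV projection plus a 7 mm margin, with an error-function
penumbra (sigma 4 mm).

The engine is a primary-fluence surrogate for the commercial collapsed
cone algorithm: per control point, dose is weight x aperture transmission
x `exp(-muEff x radiological depth)` x inverse square, with
`muEff = 0.05 / cm` (approximately 6 MV) applied to the density-weighted
path from the source. No scatter kernel is modelled. All conclusions
drawn from it are *relative comparisons between image sets under the same
engine*. Two
interchangeable path integrators are provided: a voxel-exact Siddon
traversal (reference) and a divergent ray-cast that accumulates density
along a per-beam polar lattice (2 mm lateral ray spacing at the
isocenter, 1.25 mm radial steps) and interpolates the depth per voxel.
The ray-cast engine is the default — it is several times faster and
agrees with Siddon to a fraction of a percent typically (worst-case a few
percent at sharp bone/air edges); the tests assert both the agreement and
the closed-form attenuation law for each.

The plan is finalised once on the planning CT: the isocenter is placed at
the CTV centroid, apertures are fitted there, and the plan scale is
frozen so the mean whole-breast-CTV dose equals the prescription
(42.56 Gy for the 16-fraction scheme). Every other image set reuses the
frozen scale — dose is never renormalised per image, so density errors
propagate into dose differences, which is the quantity under study.

Before dose calculation on a CBCT-derived image, voxels inside BODY but
outside the FOV are set to 1 g/cm^3, the standard clinical workaround for
the missing-anatomy problem.

DVH statistics (D1, D2, D95, D98, D99, mean) use the top-down percentile
convention — Dx is the minimum dose to the hottest x % of the ROI —
computed by sorting and linear interpolation between order statistics
(the type-7 quantile at probability 1 - x/100). Dose differences are
reported relative to the prescription with the repeat CT as reference.

Gamma analysis is global 3-D: the dose criterion is a percentage of a
fixed normalisation dose (42.47 Gy by default, kept as an independent
configuration value from the prescription), reference
voxels with dose > 0 are included, the evaluated distribution is refined
trilinearly 3-fold per voxel side, and candidates are visited in order of
increasing distance with an exact early stop inside a search radius of
3 x the distance criterion. An exhaustive brute-force implementation with
no cap serves as the oracle; equivalence is asserted to 1e-6 where the
search radius is sufficient, and the map can be run uncapped.

## The ACE risk model

Acute-coronary-event (ACE) risk is modelled on the mean heart dose (MHD)
only: each age bracket's risk is `baseline x (1 + 0.074 x MHD)`, with the
published 7.4 %-per-Gy relative slope, and a patient's risk interpolates
between the over-70 (minimum-risk) and under-40 (maximum-risk) brackets.
The bracket baselines (1 % and 10 % by default) are explicitly
configuration values, not published estimates — the underlying age tables
are in cited literature, not reproduced here. D1/D2 heart deviations are
reported in the DVH tables but do not enter the ACE number, matching the
model's definition. Because the phantom's beam geometry is a
simplification (a ball CTV with apertures fitted around it, rather than
tangent fields hugging a curved chest wall), the phantom's mean heart
dose is far higher than clinical breast values; ACE deltas between image
sets are therefore illustrative of the mechanism, not of clinical
magnitudes.

## The cohort

`runCohort()` emulates a clinical evaluation cohort at desk scale: 10 seeded
cases. Each case draws its anatomy deterministically from its seed —
deformation peak uniform in 6-12 mm, swelling or shrinkage with equal
probability, breast radius 50-60 mm, small breast/heart position jitter —
because a clinical cohort consists of *distinct patients* sharing only the
inclusion criterion. With identical anatomy across cases the between-case
variance collapses and the tiny deterministic biases of the good
correction methods (about 0.1 % of prescription) would masquerade as
systematic effects; varying the anatomy restores the variance structure
cohort statistics rely on. Scanner and artifact parameters stay
fixed across the cohort, as properties of the imaging chain.

The cohort report aggregates, per method: MAE/ME (mean, sd, range) in the
CBCT-ROI (FOV eroded by 2 cm, intersected with BODY — the erosion is 3-D
by default with an in-plane-only flag, since the source procedure does
not specify the cranio-caudal handling) and the whole-breast CTV; dose
differences relative to prescription for the whole-breast CTV, boost CTV
and heart; gamma passing rates at 2 %/2 mm, 3 %/3 mm, 5 %/5 mm; and
pooled-variance two-tailed t-tests of each image set against the repeat
CT.

## Numerical choices and degenerate inputs

* World coordinates are mm; voxel indices address voxel centers; masks
  are defined at voxel centers. Resampling fills use air (-1000 HU) for
  HU, 0 for dose/density, FALSE for masks.
* Erosion/dilation run on the anisotropic world-space Euclidean distance
  transform (a lower-envelope algorithm per axis), not voxel counts.
* Multilevel Otsu is exact (dynamic programming), so a phantom with six
  distinct plateaus is always partitioned perfectly; a constant image is
  rejected with an error, as fewer distinct grey levels than classes
  cannot be thresholded.
* The joint-histogram conversion drops columns below 0.1 % support,
  breaks modal ties toward the lower HU bin, and clamps outside the
  anchor range. Fewer than two surviving anchors is an error.
* Empty ROIs are errors for MAE/ME/DVH (the statistics are undefined);
  the CBCT-ROI builder instead warns and returns an empty mask, since an
  empty evaluation region is a legitimate geometric outcome.
* A two-sample t-test with zero pooled variance returns p = 1 when the
  means agree.
* Gamma with an all-zero reference errors (no included voxels).

## Problem sizes

The shipped tests and the acceptance script run: unit tests on
48 x 48 x 24 voxel phantoms at 5 mm spacing; the correction-recovery and
cohort analyses on the default 128 x 128 x 64 grid at 2.5 mm; gamma
oracle checks on 16^3 dose grids; a 10-case cohort. These sizes were
chosen so a full run completes in minutes on a single CPU while every
organ remains well resolved.

## Known limitations

* The dose engine is primary-fluence only; absolute DVH values are not
  collapsed-cone accurate, and only relative comparisons between image
  sets are meaningful.
* The phantom's heart dose is unrealistically high for breast technique
  (see above), so ACE deltas are mechanism demonstrations.
* The deep-learning correction route of the original four-method
  comparison is out of scope (it requires GPU-scale training data and
  infrastructure); the pipeline accepts an externally supplied synthetic
  CT wherever a corrected image is consumed.
* Rigid registration assumes both images share a grey-level scale; for
  raw CBCT it should be run after conversion, or bypassed with a known
  transform, which is what the pipeline defaults do.
* NIfTI I/O expects axis-aligned volumes in the package's patient
  convention; arbitrary orientations are rejected rather than silently
  reoriented.
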