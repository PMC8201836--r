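---
title: "Virtual-rod SFRT boost planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-rod SFRT boost planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

In locally advanced cervical cancer the curative boost after pelvic external-beam
radiotherapy (EBRT) is normally delivered with brachytherapy (BT): an
intentionally *heterogeneous* dose, very hot near the sources and falling off
steeply, prescribed at the 90% coverage level of the high-risk clinical target
volume (CTV). Where BT is not available or not feasible, uniform stereotactic
external-beam boosts have shown worse outcomes and more toxicity. Spatially
fractionated radiotherapy (SFRT) offers a middle road: deliberately
heterogeneous external-beam dose with hot "peaks" inside the target and cooler
"valleys" between them.

`rodsfrt` implements a virtualised SFRT approach in which the peaks are seeded
by **rods** — cylindrical (or spline-bent tubular) sub-structures placed
inside the CTV and used as high-dose optimisation objectives — together with
the complete dosimetric evaluation chain used to judge such plans: cumulative
DVH metrics (D90%, D2cm3, V45Gy, V60Gy), prescription normalisation, EQD2
conversion with cumulative EBRT+boost constraints, and coverage-mitigation
renormalisation. Because no patient data ship with the package, a
deterministic synthetic pelvic phantom generator stands in for planning CTs.

## The planning model, stage by stage

### Synthetic phantom

The CTV is a super-ellipsoid (exponent 2.5) with semi-axes $(a, a, 2a)$,
sheared anteriorly along $z$ so that its long axis curves like an anteverted
uterus; the default bend is 30 degrees. The shear is volume-preserving, so the
semi-axes can be calibrated by bisection against the voxelised volume; the
generator hits the requested volume to about 0.2%, far inside its 5% contract.
Four organs at risk are simple primitives at anatomical offsets with ±2 mm
seeded jitter: bladder (ellipsoid, anterior), rectum (cylinder, posterior),
sigmoid (tilted cylinder, posterior-superior), bowel bag (ellipsoid,
superior). Every OAR is trimmed against the CTV expanded by `oar_gap_mm`
(default 5 mm) and against previously placed organs, so the structure set is
pairwise disjoint by construction.

Defaults follow the clinical setting the package emulates: CTV volume 51 cm³
(cohort median; cohorts draw uniformly from 30–90 cm³), grid spacing 1.25 mm
so that a 5 mm rod spans four voxels (2.5 mm, a typical dose-grid resolution,
is available by configuration).

What the phantom deliberately does **not** emulate: CT/MR intensities,
deformable anatomy, patient-specific OAR–CTV distances (the offsets are free
parameters, not calibrated to any cohort). Consequences are discussed under
*Limitations*.

### Rod geometry

Straight rods are parallel cylinders of diameter 5 mm on a square lattice of
pitch 15 mm (leaving a 10 mm edge-to-edge gap) in the plane perpendicular to
the rod axis. The axis is +z rotated first by `angle_zx_deg` about y, then by
`angle_zy_deg` about x — the two tilt planes are standard; the composition
order is this package's documented choice. The lattice is anchored at the
projection of the target centroid plus a user offset, which makes rod
placement translation-equivariant with the target. Rods are clipped to the
target (no protrusion); with `max_rods` (default 3) the rods with the
greatest within-target length are kept, the most central one always included
and listed first, matching the template of one long central rod plus shorter
lateral rods. Equal lengths are broken by lattice-key order, which is
deterministic.

Bending rods interpolate two or more seed points with a natural cubic spline
(chord-length parameterised, arc-length resampled at a quarter voxel) and
sweep the centreline with a sphere. Curvature is estimated from second
differences; when the curvature radius drops below the tube radius, the tube
self-overlaps and a warning is raised (volume is never double-counted because
voxelisation is a set membership test).

Voxelisation rule, everywhere: a voxel belongs to a structure iff its
*centre* is inside the ideal geometry. This is simple, testable and
resolution-convergent; at 1.25 mm spacing a 5 mm cylinder's voxelised volume
is within a few percent of $\pi r^2 L$ and converges as the grid refines.

The valley (cooling) structure is the boolean difference between the target
and the rod union expanded by `margin_mm`. The margin is only qualitatively
specified in the clinical workflow ("some additional margin"); the default
here is 3 mm, chosen so that the valley starts roughly one deliverability
kernel sigma away from the rod surface and still dominates the target volume
at the default rod pitch.

### Surrogate dose optimizer

The commercial VMAT optimisation and transport chain (arc sequencing, MLC
modelling, Acuros-type dose calculation) is out of scope and is replaced by a
deliberately simple surrogate, stated prominently here: the package's claims
concern the rod method and the evaluation chain, not beam modelling. Dose is
modelled as

$$ D = G_\sigma \, x, \qquad x \ge 0, $$

a non-negative per-voxel intensity convolved with an isotropic Gaussian
kernel ($\sigma$ = 3 mm by default, roughly a clinical penumbra at depth).
The kernel is what makes a 5 mm-peak/10 mm-gap pattern non-trivial: arbitrarily
sharp dose is impossible, mirroring the resolution argument that very narrow
apertures carry dosimetric uncertainty. The kernel is separable, truncated at
4σ and row-normalised, so constants are reproduced exactly, an interior point
source keeps its mass to <0.1%, and the output never exceeds the input
maximum.

The optimizer minimises a weighted quadratic penalty by projected gradient
descent on $x$:

* CTV voxels below the prescription (30 Gy) — all strategies;
* rod voxels below `rod_min_gy` (default 60 Gy, explored range 60–80;
  per-rod dose levels may override this via an attribute) — SFRT_1 and
  SFRT_2;
* valley voxels above `valley_max_gy` (default 45 Gy) — SFRT_1 only;
* each OAR's hottest-2 cm³ voxel set above its limit, the set recomputed
  every iteration (an almost-everywhere-differentiable surrogate of the
  D2cm3 constraint);
* squared dose outside the CTV expanded by 20 mm (dose-bath decay);
* optionally, a coverage structure (PTV2mm) below the prescription — the
  re-optimisation mitigation.

Numerical choices: the gradient with respect to $x$ is $G_\sigma^\top g = G_\sigma g$
(the kernel is symmetric); the step is `step_size / (2 Σw)`, which bounds the
step by the inverse of the penalty Hessian's norm (each voxel's curvature is
at most $2\Sigma w$ and $\|G_\sigma\| \le 1$), so fixed-step descent is stable at the
default `step_size = 1`; intensity starts uniform at the prescription inside
the CTV + 5 mm; the iteration budget is fixed at 300. The algorithm is
entirely deterministic — the config's `seed` is recorded for provenance. If
the objective has not decreased over the final 10% of iterations a warning
with diagnostics is raised and the best iterate is returned.

With the default weights (`ctv` 1, `rod` 1, `valley` 1, `oar` 4, `bath` 0.05)
the peak-and-valley strategy reaches mean rod doses of ≈58–60 Gy against
valley means of ≈36 Gy (ratio ≈1.6) on the default phantom; weights were
fixed once at values that realise the stated objectives and are exposed for
experimentation.

### DVH metrics and normalisation

Cumulative DVHs use 0.02 Gy bins. Metrics interpolate linearly between bins
(the binning is specified by the evaluation protocol; the interpolation is
this package's choice). D2cm3 uses absolute volumes from voxel counts — no
partial-volume weighting, consistent with binary-mask voxelisation — and,
in plan evaluation and mitigation, is computed as the exact voxel order
statistic: that makes it *exactly* linear in a global dose scale, the
property the closed-form mitigation relies on. Coverage (D90%) is read from
the binned curve, because that is the reading the prescription targets.
Prescription normalisation starts from the closed-form factor
`target / current D90` and then refines it by bisection: with fixed bin
edges the binned reading of a rescaled plan is a step function of the
scale, and the bisection lands on the nearest achievable reading — within
half a bin (±0.01 Gy) of 30 Gy, and typically within 10⁻⁴ Gy at clinical
structure sizes. Average DVHs carry symmetric 1·SD and 1.95·SD bands
clipped to [0, 1].

### EQD2 arithmetic

The linear-quadratic conversion
$EQD2 = nd\,(1 + d/(\alpha/\beta))/(1 + 2/(\alpha/\beta))$
with $\alpha/\beta$ = 10 for the CTV and 3 for OARs is applied to scalar DVH
metrics (not voxel-wise — matching how the cumulative constraints are
defined), and its inverse is the positive root of the corresponding quadratic
in dose per fraction. Two decisions deserve note:

* **Prior course fractionation.** The prior EBRT phase is 45 Gy in 25 × 1.8 Gy
  by default. Only this choice reproduces the cumulative CTV objective of
  84.25 Gy (40 + 44.25) and recovers the printed boost limits
  23.75/17.0/19.5/17.0 Gy from the cumulative limits 80/65/70/65 Gy to
  within 0.05 Gy. A 2 Gy/fraction prior is available by configuration.
* **Cumulative-limit assignment.** Published text and table disagree on
  whether 80 Gy belongs to the bladder or the rectum; the assignment used
  here (bladder 80, rectum 65) is the only one consistent with the
  inverse-EQD2 arithmetic of the boost aims, and is shipped in
  `inst/extdata/objectives.yaml`.

A related rounding note: the sigmoid boost aim prints as 19.5 Gy while the
inverse conversion of 70 Gy gives 19.45 Gy; the package keeps the printed
aim and the 0.05 Gy consistency tolerance absorbs the difference.

### Plan evaluation and mitigation

`evaluate_plan()` flags aim-level and hard-limit violations separately
(D-metric aims tolerate half a DVH bin — the normalisation guarantee; all
other comparisons are at float precision). The renormalisation mitigation
exploits the same linearity as the prescription normalisation: the largest
safe global scale is `s* = min over OARs of (hard limit / D2cm3)`, closed
form, with the binding organ ending exactly at its limit — a search, as a
clinical system would perform, necessarily converges to the same point.
The re-optimisation mitigation adds a PTV2mm coverage objective and then
renormalises. Cohort summaries report mean ± sample SD (n−1) and [min, max]
per metric.

## Problem sizes used by the shipped tests

The test suite exercises the full default-resolution chain (1.25 mm grid,
≈0.9 million voxels, 300 iterations) once per strategy for the
normalisation and uniform-coverage checks, and uses a 2.5 mm phantom
(≈120 000 voxels) for geometry, optimizer-property and 5-phantom cohort
tests. These sizes were chosen as the smallest on which the geometric
contracts (half-voxel pitch tolerances, 3% volume oracles) are meaningful.

## Known limitations

* **The optimizer is a surrogate.** A single Gaussian kernel has no
  entrance/exit channels, scatter tails or arc geometry, so the dose bath
  beyond ≈10 mm from the CTV is far lower than a real three-arc VMAT plan
  produces. OAR D2cm3 values on the phantom are therefore several-fold lower
  than clinical values, and the mitigation headroom (the scale to the first
  binding OAR) is correspondingly exaggerated. Trend statements — peak-only
  covers more of the 45 Gy level than peak-and-valley, uniform plans have no
  200% hotspot, mitigation raises coverage above the prescription — are
  meaningful; absolute OAR doses are not.
* Passing tests on the phantom say nothing about real contours: the phantom
  has idealised convex organs at fixed distances.
* Binary masks without partial-volume weighting bias small-structure volumes
  at coarse spacing; use 1.25 mm or finer for sub-centimetre structures.
* Contour export serialises RT-structure-style geometry (per-slice closed
  polygons in patient mm) as JSON; it does not emit binary DICOM files.
  Nested contours re-voxelise by the even-odd rule; self-intersecting
  polygons are not supported.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from a fresh phantom at the default
resolution: the cumulative CTV EQD2 chain (84.25 Gy), the normalised CTV
D90% of the peak-and-valley plan (30 Gy target, ±0.01 Gy), and the CTV
V60Gy of the uniform-coverage plan (0%). See the README for invocation.
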