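---
title: "Models and numerical methods in fetalflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in fetalflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalflow)
```

`fetalflow` implements the complete processing chain of volumetric,
cardiac-resolved phase-contrast ("4D flow") CMR of the fetal circulation —
from wrapped multi-VENC phase volumes to per-vessel flows, shunt streaming
and method-comparison statistics — together with an analytic phantom that
serves as ground truth for every stage. This vignette documents the models,
the tunable parameters, the numerical choices, and what the validation on
synthetic data does and does not establish about real acquisitions.

## The phantom

### Vessel network and flows

The default network (`make_default_network()`) is a stylized fetal
circulation: fourteen straight-to-polyline segments covering the umbilical
vein (UV), ductus venosus (DV), distal and proximal inferior vena cava
(IVCd, IVCp), right hepatic vein (RHV), superior vena cava (SVC), foramen
ovale (FO), main pulmonary artery (MPA), ductus arteriosus (DA), branch
pulmonary arteries (LPA, RPA), ascending aorta (AAo), brachiocephalic trunk
(BT) and descending aorta (DAo). Four junctions carry conservation-of-mass
assertions:

* IVCp = DV + IVCd + RHV (hepatic/caval confluence),
* SVC + IVCp = MPA + FO (right-heart throughput),
* MPA = DA + LPA + RPA (pulmonary bifurcation),
* IVCp = DAo (lower-body balance).

Segment mean flows are published fetal-sheep indexed values (mL/min per
kg) scaled by fetal weight (default 2.8 kg, heart rate 140 bpm). Published
per-vessel means, being averages over different subject subsets, are not
mutually mass-conserving (e.g. MPA 284 vs DA + PBF 303 mL/min/kg); a
phantom, however, must conserve mass exactly or it cannot oracle the
junction checks. The package therefore keeps the published values for UV,
DV, IVCd, SVC, MPA, AAo, DAo and the pulmonary branches, and *derives* the
remaining flows from the junction balances: IVCp = DAo = 333, RHV = 333 −
144 − 117 = 72, FO = 181 + 333 − 284 = 230, DA = 284 − 38 = 246 (all
mL/min per kg). The constructor enforces every junction balance to 0.1%
(`network_spec(..., renormalize = TRUE)` repairs an unbalanced junction by
rescaling its outflows).

Conservation is asserted on **cycle means**, not per frame. Venous return
(biphasic SVC/IVCp waveforms) and arterial output (peaked MPA waveform)
cannot balance instantaneously at the right heart — the atria and
ventricles buffer volume within the cycle — and the in vivo consistency
checks this package reproduces are themselves computed on cycle-mean
flows. Junction blending regions in the rasterized field are therefore
mildly compressible within a cycle; analysis planes sit mid-segment, away
from them.

### Waveforms

Three template classes cover the morphologies of fetal flow curves:

* `arterial` — a raised-cosine systolic lobe of width `peak_frac`
  (default 0.35 of the cycle) over a diastolic baseline, with
  `peak_to_mean` (default 2.8) setting the pulsatility;
* `venous_biphasic` — two unequal raised-cosine lobes (the S- and D-waves
  of central venous return), `second_peak_ratio` default 0.6,
  `peak_to_mean` default 1.6;
* `constant` — flat (umbilical venous return is nearly decoupled from
  intracardiac pressure).

No quantitative waveform equations are available for the fetal-sheep
curves, so the shapes are parameters rather than fits. Every waveform is
renormalized so its *continuous* cycle mean equals `mean_flow` to better
than 0.1%. Note that the mean over 8 uniformly spaced cardiac frames of a
pulsatile template differs from the continuous mean by up to ~0.8%
(quadrature error of coarse cardiac sampling); real 8-frame acquisitions
share this property, and it sets the floor for the phantom's
junction-consistency residuals at the measured level. In the default
network the arterial systolic peak is phased onto a sampled frame
(`phase_shift = -0.05`) so that the 8-frame data actually attain the
design peak velocities (~135–145 cm/s in the great arteries, above the
low VENC and safely below the high VENC).

### Rasterization

Each segment carries a Poiseuille profile: axial velocity
`v(d) = 2 Q / (pi R^2) * (1 - (d/R)^2)` at distance `d` from the
centerline, oriented along the local tangent and scaled per frame by the
waveform flux. Voxel values are, by default, *partial-volume averages*
over a 3×3×3 sub-grid per voxel (`supersample = 3`): MR voxels average
the spin velocities they contain, and this choice makes the discrete flux
of a tube agree with the analytic flux to ~0.2% even at 3.5–4 voxels per
diameter, where pointwise center sampling errs by several percent.
`supersample = 1` gives exact pointwise sampling (used where tests need
the analytic profile voxel-for-voxel). Where segments overlap — within
about one radius of a junction — the velocity is the flux-weighted average
of the overlapping fields, a C0 blend sufficient for mid-segment
measurement. A `plug` profile option (uniform axial velocity) exists for
the streaming phantoms, where particle routing must be exactly
flux-proportional under uniform-area emission.

Voxel centers sit at `(index − 0.5) * spacing` with the world origin at
the volume corner; coordinates are mm, velocities cm/s, time ms.

### MR encoding

Per voxel, component and frame the stored phase is
`wrap(pi v / VENC + background)` into `(-pi, pi]`; velocities beyond the
VENC alias. The background is a per-component polynomial (default order 1)
over voxel coordinates normalized to `[-1, 1]^3`, emulating eddy-current
phase offsets; its order is configurable so the correction's
order-matching can be tested. Magnitude is 1.0 in the lumen, 0.7 in
tissue and 0.05 in air (arbitrary but fixed levels chosen so
static-tissue detection is exercisable); tissue fills the volume except a
6 mm air shell. At finite SNR, independent Gaussian noise of standard
deviation `1/SNR` radians perturbs the phase (the small-angle
approximation of complex Gaussian noise) and the same SD perturbs the
magnitude. Encoding is bit-reproducible for a fixed seed.

## Reconstruction

* **Phase to velocity** — `v = VENC * phi / pi` per component.
* **Static-tissue detection** — voxels whose temporal phase SD (every
  component) is below `phase_std_max` (default 0.1 rad) and whose
  time-mean magnitude exceeds `mag_min` (default 0.3) of the volume
  maximum. Two caveats are inherent to any threshold rule of this form:
  constant-flow lumen (e.g. the UV) has zero temporal phase variation and
  will be included, and a parabolic profile always has a thin near-wall
  shell whose slow flow is indistinguishable from tissue. The first is
  handled downstream (robust fitting); the second is why the exact
  mask-recovery test uses a plug-profile phantom.
* **Background correction** — per component, a polynomial of configurable
  order (default 1, the common eddy-current choice) in normalized voxel
  coordinates is least-squares fit to the time-mean velocity over static
  voxels and subtracted everywhere. With `robust = TRUE` (the pipeline
  default) the fit iteratively discards voxels whose residuals deviate
  from the median residual by more than `outlier_k` (default 4) robust
  SDs — centring on the median matters, because a contaminated fit
  offsets *all* residuals; an absolute floor of 1e-3 cm/s prevents a
  noise-free fit from flagging round-off, and trimming never removes the
  majority. Matching-order contamination with a clean mask is removed to
  machine precision, and the operation is idempotent.
* **Unwrapping** — temporal first: per voxel/component, each frame is
  shifted by the multiple of `2 VENC` minimizing the jump from the
  previous frame. Then spatial: a wavefront grown from trusted seeds (the
  static mask, else all voxels with time-mean speed below VENC/2)
  compares each new voxel's time-mean to the median of already-processed
  6-neighbours and shifts the whole series by the nearest multiple of
  `2 VENC` when the gap exceeds the VENC. Every change is an exact
  multiple of `2 VENC` (assertable), and unaliased data pass through
  bit-identical. The wavefront processes whole frontier shells at a time —
  a vectorization-friendly order that is deterministic for fixed input.
* **Dual-VENC merge** — keep the precise low-VENC value where it agrees
  with the unwrapped high-VENC value within one low VENC (ties kept on
  the low side, deterministically); otherwise shift it by the nearest
  multiple of `2 VENC_low` toward the high value; if still discrepant,
  fall back to the high value and flag the voxel. The decision is per
  component by default; `per_vector = TRUE` makes one decision per voxel
  from the largest component disagreement (the published description of
  the vendor merge is ambiguous between the two).
* **Angiogram** — intensity is the time-mean of magnitude × speed; the
  lumen is the 6-connected component(s) above `threshold` (default 0.1)
  of the maximum, grown from user seeds or the global maximum.

On a noise-free dual-VENC phantom with a linear background and speeds
between the two VENCs, the full chain returns the ground truth to ~1e-7
cm/s; the residual is pure floating-point accumulation.

## Quantification

Analysis planes resample the field on a square in-plane grid at half the
smallest voxel spacing (trilinear interpolation; pixels outside the
volume are excluded and counted). The default lumen mask is the disk of
the vessel radius plus a 1.5 mm margin: the rasterized vessel's
partial-volume edge carries real flux, and because the exterior field is
zero the margin adds no spurious signal — only neighbouring vessels
could, which is why the default network keeps planes clear of other
segments. Per frame, `q = sum((v . n) * pixel_area)` in mL/s; the cycle
mean (×60) gives mL/min, divided by fetal weight gives indexed flow.
`align_plane()` iterates the normal onto the direction of the mean lumen
velocity, mirroring the manual adjustment of contours until vectors are
perpendicular to the cross-section.

Derived quantities: PBF = LPA + RPA; CVO = 1.03 × (MPA + AAo), the 3%
accounting for unmeasured coronary flow; %CVO as integer percentages
rounded half away from zero (matching the published tables' integer
presentation). Junction checks use the symmetric percent difference
`100 |ΣQin − ΣQout| / ((ΣQin + ΣQout)/2)` — the mean-denominator choice is
configurable (`denominator = "inflow"`), since published reports rarely
state it. A missing vessel skips the check with a recorded reason rather
than failing, as in cohorts where not all vessels could be segmented.

One reproducibility note: published flow-distribution tables are averages
of per-subject values, so the printed CVO (546 mL/min per kg) is not
exactly `1.03*(284+245) = 544.9` recomputed from the printed MPA/AAo
means, and one vessel's printed percentage (DA, 48%) differs by one
integer from the ratio of printed means (49%). The package computes
ratios of the values it is given and documents the discrepancy instead of
adjusting it.

`compare_methods()` is ordinary least squares of method A on method B with
a normal-theory 95% slope interval, R², Bland-Altman bias ± 1.96 SD limits
of agreement, and a two-sided paired t-test (flagged undefined when the
differences have zero variance). The real-world two-method comparison is
emulated only as a synthetic scenario with an injected bias; recovering
the bias within `3·s/√n` is a sampling-theory check of the statistics
code, not a reproduction of any in vivo result.

`voxels_per_diameter(area, voxel) = 2 sqrt(area/pi) / voxel` expresses the
standard resolution adequacy check (~3 voxels per diameter needed for
reliable flow): the smallest branch-pulmonary cross-section of 21.5 mm²
spans 3.5 voxels at 1.5 mm.

## Pathlines and streaming

`velocity_at()` is trilinear in space and linear in time with periodic
wrap (the last frame interpolates onto the first, as in cine loops played
over two cycles). `trace_pathlines()` advects particles with classical
RK4 (1 cm/s = 0.01 mm/ms), default step `period / (40 × n_frames)`;
particles terminate on leaving the volume, on entering a supplied lumen
exterior, or at `duration` cycles. On a rigid-rotation field — linear in
space, hence represented exactly by trilinear interpolation — the
integrator shows clean 4th-order step-size convergence and sub-1e-4
relative radius drift per revolution at dt = period/1000; uniform-field
advection is exact. A `streamline` mode freezes the field at the release
time, since it is often unclear whether commercial visualizations
integrate pathlines or per-frame streamlines.

`streaming_matrix()` assigns each particle to the *first* sink region its
trajectory enters (so a particle transiting right atrium → FO → left
ventricle is credited to the FO — the semantics that matches
shunt-routing questions), with unassigned particles keeping row sums at
exactly 1. Sinks are boxes or spheres and must be disjoint.

The quantitative streaming oracle is a plug-flow split phantom
(`make_split_phantom()`): a channel whose downstream side is divided so
that 80% (configurable) of the flux — and, under plug flow with
uniform-area emission from the full-speed core, 80% of the particles —
enters the first sink. Emission is from one voxel inside the channel wall
because trilinear interpolation necessarily ramps the velocity to zero
across the boundary voxel; seeds in that ramp would stall and read as
unassigned. A Poiseuille profile is deliberately *not* used here:
uniform-area emission over a parabolic profile samples slow near-wall
streamlines in proportion to area, not flux, so the particle fraction
would not equal the flux fraction.

## Problem sizes and determinism

The validation suite runs the full network phantom at 96³ voxels × 8
frames × 2 VENCs (1.5 mm, the acquisition geometry it emulates), which
reconstructs in about two minutes on one CPU; unit tests use 32³–48³
grids and the streaming tests 1000 particles. All stochastic steps
(encoding noise, emission, the method-comparison scenario) are seeded;
identical seeds give bit-identical phase stacks and particle seeds.

## What the synthetic validation does not show

The phantom has piecewise-straight vessels, rigid geometry, no fetal or
maternal motion, no k-space or parallel-imaging artifacts, Gaussian phase
noise rather than full complex-signal statistics, and idealized waveform
templates. Passing its oracles demonstrates that the *processing* is
correct and internally consistent at realistic resolution and SNR — not
that any particular in vivo accuracy is achieved. Real-data effects such
as partial-volume bias at 3–4 voxels per diameter, temporal undersampling
of systolic peaks, and respiratory motion enter the in vivo error budget
in ways a desk phantom cannot arbitrate; the package's consistency
metrics (junction percent differences, dual-VENC fallback counts) are the
tools it offers for judging those effects on real data.
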