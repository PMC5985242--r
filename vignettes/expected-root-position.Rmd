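---
title: "Expected root position: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected root position: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erproot)
```

## The model and its assumptions

The expected-root-position (ERP) workflow rests on one physical
assumption: **a tooth is a rigid body**. Crown and root move together, so
a rigid transform estimated from crown surfaces alone is also the correct
transform for the root. Two further assumptions follow from the imaging
chain: CBCT segmentations and cast scans are metrically true (1:1, all
coordinates in mm — the package never estimates scale), and the crown
anatomy itself is unchanged between the pre-treatment scan and the
progress scan (a large new restoration breaks the method for that tooth).

The pipeline has two registration granularities, and the distinction is
the crux of the validation design:

* **ERP generation** fits *every tooth separately* (teeth move
  independently during treatment): landmark initialization, optional
  manual pre-transform, then ICP of the pre-treatment crown against the
  crown-only scan, with the composed transform applied to the full tooth.
* **Control superimposition** fits *one rigid body per arch* on the
  combined crowns: a progress CBCT does not tell us how teeth moved — it
  is itself the answer — so it is only brought into the scan frame as a
  whole. The maxilla and mandible are always independent rigid bodies;
  fitting both jaws together would let mandibular posture corrupt both
  arches.

Indirect superimposition then compares the ERP setup with the control in
the common scan frame. Signed displacement statistics are invariant under
any shared rigid change of frame (verified to 1e-6 mm in the tests), so
"compare in the scan frame" is equivalent to comparing in any frame — the
intermediary merely supplies the registration target both sides can reach.

## Registration components

**Landmark step (Kabsch).** Closed-form orthogonal Procrustes without
scale on ≥ 3 paired points. Degeneracy is checked by the second singular
value of the centered points (> 1e-9 mm), because collinear landmarks
leave a free rotation about the line. The reflection case
(`det(VUᵀ) = −1`) is handled with the standard sign correction; the
result is re-projected to the nearest rotation after every composition to
stop round-off drift (orthonormality is asserted to 1e-9 everywhere).

**ICP.** Point-to-point, with exact nearest points *on the target
surface* (point-to-triangle through an AABB tree; vertex-to-vertex
matching would bias the fit whenever the two meshes are tessellated at
different densities, which is exactly the CBCT-versus-laser-scan
situation). Parameters, all overridable per call:

| parameter | default | unit | why |
|---|---|---|---|
| `max_iterations` | 500 | – | point-to-point ICP converges by tangential creep; crown-scale fits need several hundred iterations to settle the pose (see below) |
| `tol` | 1e-7 | mm | change-in-RMS stop; must sit well below the per-iteration creep of an unconverged fit |
| `reject_dist` | 1.0 | mm | correspondence gate; drops points with no true counterpart (bracket/band artifacts, root points facing a crown-only target) while keeping everything that can match |
| `sample_count` | 5000 | vertices | caps cost on dense scans; drawn deterministically from `seed` |
| `seed` | 0 | – | reproducible subsampling; the caller's RNG state is restored |

The iteration defaults deserve a note. With 100 iterations and a 1e-5 mm
stop — plausible-looking values — per-tooth pose errors of up to 0.09 mm
survived on 5° perturbations, because point-to-point ICP reduces the RMS
by only a few 1e-5 mm per iteration while the pose is still rotating into
place. At 500 iterations / 1e-7 mm every synthetic tooth settles below
0.001 mm and the extra cost is a few tenths of a second per tooth. This
is a deliberate accuracy-over-speed default for a method whose entire
point is sub-millimetre root prediction.

ICP monotonicity (non-increasing RMS) holds exactly with rejection
disabled and is property-tested; with a rejection gate the accepted set
can change between iterations, so the guarantee is per-set only.

**Rotationally symmetric surfaces.** On a sphere (or a very round tooth)
the registration problem is ill-posed: many rotations fit equally well.
ICP still converges — to *a* minimizer — and the `converged` flag refers
to the RMS, not to pose uniqueness.

## Crown/root separation

The anatomical cut "at the CEJ" is modeled as an explicit plane per tooth
(fit by least squares to ≥ 3 marked CEJ points, normal oriented by a
crown-side hint). Triangles crossing the plane are split along it;
intersection points are computed once per mesh edge in a canonical vertex
order, so the crown rim and the root rim share bit-identical coordinates,
the cut is watertight as a partition (total area conserved to 1e-6
relative, tested on 100 random teeth) and each side has a single open
boundary loop. Vertices within 1e-9 mm of the plane count as lying on it;
a face entirely in the plane goes to the crown side (an arbitrary but
fixed tie-break). A plane that misses the mesh yields one empty side with
a flag, not an error.

## Signed displacement

For each test vertex the nearest point on the reference surface is found
exactly; the sign comes from the angle-weighted pseudo-normal of the
nearest feature (face, edge or vertex), which gives the correct
inside/outside decision for consistently oriented meshes even when the
nearest feature is a sharp edge — a plain face-normal test can flip sign
there. Conventions, fixed and documented because the choices are not
forced:

* positive = test vertex outside the reference surface;
* "mean" is the **signed** mean (a bias measure; near zero when errors
  are symmetric);
* "SD" is the **population** SD — the vertices are the complete
  population of the mesh, not a sample, and the choice makes test values
  exact;
* "maximum" is the maximum **absolute** signed value;
* color map: |d| ≤ 0.75 mm green (boundary inclusive), d < −0.75 blue,
  d > +0.75 red. The 0.75 mm band is the standard deviation-map
  threshold of the clinical workflow this package reproduces; the map is
  a three-class rendering, not a gradient.
* histograms: 0.25 mm bins over −2..+2 mm by default, values outside the
  range clipped into the end bins so counts always sum to the vertex
  count.

Arch-level rows pool per-vertex values across the arch's teeth,
unweighted; per-tooth rows are emitted alongside as supplementary output.

## What the synthetic generator emulates — and what it does not

`make_tooth()` builds an idealized single-rooted tooth: stacked
superellipse cross-sections (elliptical root tapering to an apex, boxier
crown with a cervical constriction and a bulge at the middle third),
closed with apex and crown-tip caps — watertight, outward-oriented and
fully deterministic. `make_arch()` places population-mean crown sizes
along a parabolic arch with mesiodistal axes tangent to the curve and a
0.8 mm inter-tooth gap, erroring if any two teeth come within 0.1 mm.
Both arches are generated with crowns up at z = 0; since arches are
processed independently, jaw orientation is a convention, not a model
choice. `simulate_treatment()` applies clinically parameterized movements
(tip / torque / rotation about tooth-local axes through the crown
centroid, plus translation) and returns the exact transforms.
`simulate_scan()` degrades meshes with Gaussian noise along vertex
normals (scanner error is predominantly radial to the surface) and
random face removal emulating incomplete coverage; `pick_landmarks()`
emulates manual point picking by farthest-point sampling with optional
Gaussian click error.

The default study conditions used by the validation (both the acceptance
tests and `scripts/acceptance.R`) are: 14 teeth per arch at mesh
resolution 4 (≈ 1500 vertices per tooth), per-tooth movements drawn
uniformly within ±2° of tip/torque/rotation and ±0.5 mm of translation
(typical bracket-repositioning corrections), landmark click error sd
0.3 mm, and for the degraded variant crown-scan vertex noise sd 0.05 mm
with 50% face decimation — values chosen once as representative of
laser-scan accuracy and never tuned. These sizes keep the full test suite
and the acceptance script in the low minutes on one CPU.

What passing these tests shows: the geometry kernel, the registration
stack and the reporting are correct, and the crown-only transfer recovers
rigid ground truth through realistic levels of noise, decimation and
landmark error. What they do **not** show: performance on real anatomy.
Real teeth have individual crown morphology, partially erupted or rotated
neighbours, bracket and band artifacts fused to the crowns, segmentation
bias at the gingival margin, and non-rigid errors of the impression/cast
chain — none of which the parametric generator reproduces. Bracket-like
surface bumps can be emulated separately, but are off by default; the
correspondence-rejection gate is the mechanism that handles them.

## Degenerate inputs and numerical edges

* Meshes must have ≥ 1 face, finite coordinates, in-range indices and no
  topologically degenerate (repeated-index) faces; zero-*area* faces are
  tolerated except as the entire reference of a displacement query.
* Rotation validity (orthonormality, det +1) is enforced to 1e-9 at
  construction, so an accidental reflection can never enter the pipeline;
  transform JSON is validated on read.
* Rotation *error* comparisons in the tests are made on matrix entries,
  not on the `acos`-derived angle, whose double-precision floor
  (≈ 2e-8 rad) would mask genuinely exact recovery.
* PLY is written binary little-endian with double-precision coordinates:
  float32 would already exceed a 1e-6 mm round-trip budget at crown-scale
  coordinates. STL is written ASCII at full precision and re-indexed on
  read by exact coordinate match.
* ICP raises a dedicated correspondence-starvation error when fewer than
  three pairs survive the rejection gate, rather than silently fitting
  to noise. Per-tooth failures in ERP generation exclude the tooth with a
  recorded error and a warning — extractions and unregistrable teeth are
  expected in clinical data — and never abort the arch.

## Known limitations

* Point-to-point ICP with landmark initialization has a small capture
  range (≈ 5° / 1 mm of residual pose after landmarks); grossly wrong
  landmarks are not recovered from. The optional per-tooth manual
  pre-transform exists for exactly the cases a human would nudge first.
* The CEJ plane is a planar surrogate for a curved anatomical line; root
  statistics near the rim depend slightly on its placement. Both compared
  meshes are cut with the *same* plane, which removes most of that
  sensitivity from the comparison.
* The displacement sign convention needs consistently oriented reference
  normals; for open scan fragments the orientation is taken as given.
* Multi-rooted teeth are generated as single-rooted shapes; nothing in
  the registration or reporting depends on root count, but the synthetic
  realism is lowest for molars.
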