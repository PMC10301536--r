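---
title: "Volumetric cephalometry: model, geometry engine, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric cephalometry: model, geometry engine, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volcephalo)
```

## The analysis

The quantity of interest is the distribution of facial soft-tissue volume
across four anatomically meaningful regions of the lower two-thirds of the
face. Given a watertight skin-surface mesh (mm) and thirteen named
cephalometric landmarks, the pipeline cuts the mesh with six planes:

* **Frankfort horizontal (FH)** — through both porions and the left
  orbitale; when a right orbitale is supplied, a four-point
  total-least-squares fit. Superior cut of the region of interest.
* **Bi-porion coronal** — contains both porions and the head's vertical
  axis; posterior cut.
* **Bispinal (palatal)** — ANS–PNS is a line in 3D, so the cutting plane
  is completed with the head frame's lateral axis: a transversely level
  palatal plane, the classical 2D palatal line lifted to 3D with no roll.
* **Occlusal** — exact plane through one anterior and two molar occlusal
  points (classical functional occlusal plane with minimal landmark
  burden).
* **Mental foramina** — an FH-parallel plane cannot in general contain
  both foramina, so it passes through their midpoint and the per-foramen
  residuals are reported.
* **Mandibular base** — through both gonions and menton; separates the
  face from the neck with a single oblique plane.

The lower two-thirds is the solid below FH, anterior of the coronal plane
and above the mandibular base. It is partitioned by a fixed cut tree —
palatal first, then occlusal, then foramina — so the four slabs (malar,
maxillary, mandibular, chin, top to bottom) are **exact by construction**:
their volumes sum to the lower-two-thirds volume to machine precision
rather than within some meshing tolerance. Soft tissue is measured as the
full solid enclosed by the skin within each slab; bone and air cavities
are not subtracted.

Per subject the report is the four volumes (mm³), the percentage shares
$s_i = 100\,V_i/\sum_j V_j$, and the maxillomandibular ratio
$V_{max}/V_{mand}$. At the cohort level, gender summaries take the
arithmetic mean of each slab volume and derive shares **from the mean
volumes**, not as the mean of per-subject shares — the only convention
under which the embedded female reference percentages are exactly
consistent with the female reference volumes. Shares are printed
half-away-from-zero at 1 decimal, ratios at 2, matching the precision of
the embedded references.

## Orientation and ordering conventions

All plane normals are semantically oriented: horizontal planes point
superior, the coronal plane points anterior. The head frame places its
origin at the mid-porion point; `up` is the FH normal oriented so ANS has
a negative up-coordinate, `anterior` is the in-FH direction toward ANS,
and `left = up × anterior`. Every measurement is invariant under rigid
motion of mesh and landmarks together (tested to 1e-6 relative).

Before segmenting, the plane stack is validated along the vertical line
through ANS: FH ≥ palatal ≥ occlusal ≥ foramina, menton on or below the
foramina plane, ANS below FH and anterior of the coronal plane.
Violations are reported with signed gaps in mm and segmentation refuses to
run unless forced.

## The geometry engine

Meshes are plain vertex/face arrays; watertightness means every directed
edge is matched by its reverse exactly once. Volume is the signed
tetrahedron sum; a negative total triggers orientation repair (flip all
faces with a warning — STL exporters disagree on winding) rather than an
error.

**Plane cutting.** Vertices within 1e-9 mm of the plane are snapped onto
it before splitting, which avoids sliver triangles; a vertex exactly on
the plane belongs to both pieces. Crossing triangles are split with
intersection points cached per undirected edge, so adjacent triangles
share identical cut vertices and both pieces are watertight by
construction. The open cross-section boundary is chained into closed
loops, projected into the plane, and triangulated by ear clipping with
earcut-style hole bridging (nested loops classified by even–odd
containment). Collinear boundary runs — the generic case when a cut
crosses a triangulated flat face — produce zero-area cap ears; these are
emitted rather than dropped, because dropping them would break
boundary-edge pairing. If ear clipping fails numerically, a centroid-fan
fallback caps the loop group; fan triangles may overlap geometrically but
their signed areas cancel exactly, so enclosed volume and combinatorial
watertightness are both preserved.

**Voxel oracle.** An independent volume estimator counts voxel centers
inside the mesh, deciding inside/outside per vertical column by the
winding number of signed upward-ray crossings (so coplanar overlapping
fallback caps cancel correctly). The grid origin is jittered by an
irrational fraction of the spacing to avoid edge hits. The absolute error
is bounded by the surface area times the voxel size; tests require
agreement with the signed-tetrahedron volume within that bound on convex
and non-convex solids, and 2% relative on the synthetic head at 1 mm.

## The synthetic generator

Real CBCT-derived meshes are not redistributable, so the study conditions
are emulated: 26 female and 20 male subjects, 6 judges × 2 sessions, a
selection cutoff of 8.5 on the 1–10 scale. The head is a loft of
superellipse cross-sections (exponent 2.4 by default) from cranium to
neck, closed with apex cones — deliberately *not* photorealistic. What it
does guarantee: watertightness at any resolution, a valid plane stack with
mild anatomical tilts (posterior-up occlusal tilt 2 mm, gonions 8 mm above
menton, ±1 mm foramen asymmetry), and a **tunable slab distribution**.

The three interior plane heights are the calibration handles: moving one
plane only reassigns volume between its two adjacent slabs, so sequential
top-down bisection on cumulative shares is well-posed and monotone. The
calibration loop runs through the package's own measurement pipeline
(generate → extract → cut), aiming at 0.1 pp internally and verifying the
final spec end-to-end against a 0.5 pp contract. Global scale is a
separate exact handle (volumes scale with the cube, shares are invariant).

Cohorts draw per-region volumes independently from
`Normal(preset, cv · preset)` truncated at 3σ and at zero (default CV
8%, a realistic inter-subject spread for regional soft-tissue volumes;
only normality of the regional volumes is being emulated, so independence
is the minimal assumption). Jury scores follow a latent-attractiveness
model: subject latent `N(μ, σ)`, fixed judge bias, and session noise with
`sd = σ√(1/r − 1)` so the expected test–retest Pearson correlation equals
the target `r` before half-point rounding and clipping to [1, 10]; with
`r = 1` the second session duplicates the first exactly. Rounding and
clipping attenuate the realised correlation slightly below the target,
visibly so when `σ` is small relative to the half-point grid.

What passing tests on these synthetic cohorts do **not** show: robustness
to real CBCT segmentation artefacts (non-manifold patches, scan noise),
to landmark placement error, or to anatomies far from the loft family.
The geometry engine's contracts (conservation, watertightness, rigid
invariance, oracle agreement) are anatomy-independent; the calibration
contract is specific to the loft.

## Numerical choices

* On-plane snap tolerance 1e-9 mm; vertex-merge tolerance at STL import
  1e-6 mm (STL is a triangle soup).
* Degenerate-face rejection (area ≤ 1e-12 mm²) applies at file import;
  caps may legitimately contain zero-area triangles (see above).
* Shapiro–Wilk uses Royston's AS R94 approximation via
  `stats::shapiro.test()`; Pearson repeatability uses
  `stats::cor.test()`. Judges with zero variance are reported undefined
  and excluded from the mean with a warning, not silently dropped.
* Half-away-from-zero rounding is implemented explicitly
  (`round_half_away()`); base R's `round()` rounds half to even, which
  would print 26.45% as 26.4%.
* The bundled references store the published male shares verbatim with
  flags, because the printed malar/maxillary percentages (37, 26, summing
  with the others to 99) contradict the printed male mean volumes (which
  give 36.5 and 28.0); the `volume_consistent` variant recomputes shares
  from the volumes and is the default for comparisons and for the male
  simulation preset.

## Problem sizes

Default single-head resolution is 48 cross-section segments at 4 mm ring
spacing (≈ 4 900 faces; calibration ≈ 1.5 s). Cohort simulation uses 36
segments at 5 mm (≈ 1 s per calibrated subject, ≈ 70 s for the 46-subject
study). Property tests run 20 randomized heads at 24 segments / 8 mm.
These sizes were chosen so the full suite and the acceptance script each
run in a couple of minutes on one core; volumes converge with resolution
and the percentage shares converge much faster still, because the
polygonal area deficit is nearly a common factor across slabs.

## Known limitations

* No mesh repair beyond orientation flip and vertex merging; a scan with
  holes must be repaired upstream.
* A single oblique gonion–menton plane separates face from neck; per-side
  neck cuts are not modelled.
* Left/right sub-partitioning, surface-area metrics, and skeletal-volume
  subtraction are out of scope.
* The normative references describe one surgical, Caucasian, adult cohort
  selected for attractiveness; they are reference points for the method,
  not population norms.
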