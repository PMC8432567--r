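---
title: "Models and methods behind orthoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orthoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoflow)
```

orthoflow implements the computational spine of a fully digital
orthognathic-surgery workflow: dentition-to-CT fusion, natural head
position (NHP) reproduction from one photograph, rigid planning and
simulation of bone segments, and landmark-based accuracy evaluation. This
vignette documents the models, the conventions, the tunable parameters,
and the choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinate frame and Euler convention

All geometry lives in a right-handed millimetre frame with +x toward the
patient's left (the left–right axis), +y anterior (advance–setback), and
+z superior (impaction–elongation). Rotations are summarised as Euler
angles about **fixed (extrinsic) axes**,

$$R = R_z(\mathrm{yaw})\; R_y(\mathrm{roll})\; R_x(\mathrm{pitch}),$$

with degrees at every interface and radians internally. Clinical sources
name the axes (pitch about x, roll about y, yaw about z) but rarely the
composition order; at the angles involved here (mostly below 13°) the
orders agree to first order, and this package uses the z–y–x convention
everywhere — composition, decomposition, plan summaries, occlusal
discrepancies. Decomposition is unique away from |roll| = 90°; at gimbal
lock the yaw is set to 0, the remaining angle folded into pitch, and a
`gimbal_lock` attribute raised with a warning. Surgical rotations never
approach lock; the tie-break exists so the function is total.

`superpose_rigid()` is the SVD (Kabsch/Horn) closed form with the
determinant-correction step, so reflections are impossible even for
mirrored inputs; it refuses fewer than three points or collinear
configurations, where the rotation is not identifiable.

## Registration

**Trimmed ICP.** The "modified" ICP used throughout is point-to-point ICP
with two robustness devices: correspondences farther than `max_distance`
are rejected, and the worst `trim` fraction (default 0.1) of the survivors
is discarded before each SVD fit. Setting `trim = 0`,
`max_distance = Inf` recovers the textbook algorithm. Correspondence is
vertex-of-source to nearest vertex-of-target, found exactly with a k-d
tree written in C++; point-to-surface metrics would converge faster on
coarse meshes but are not needed at the fixture resolutions used here —
a documented limitation for very sparse real meshes. Convergence is a
change in kept-pair RMS below `tolerance` (default 1e-6 mm, cap 100
iterations); the kept-pair RMS is non-increasing by construction.

Point-to-point ICP has a capture basin of a few degrees/millimetres on
smooth anatomy. The package therefore treats ICP as a *refinement*: the
fusion pipeline assumes the optical scan arrives roughly pre-aligned with
the CT frame (as it does in practice), any solver accepts an explicit
`init` transform, and the evaluation pipeline builds its own
initialisation (below). No solver uses internal randomness.

**Rigid CPD.** Coherent point drift treats the moving points as Gaussian
mixture centroids with one shared isotropic variance σ² plus a uniform
outlier component of weight `w` (default 0.1). The E-step computes
posteriors; the M-step solves the rigid closed form and re-estimates σ²
with the symmetric update valid whether or not the optional isotropic
scale is estimated (`estimate_scale` defaults off — scan and CT are both
metric mm of the same anatomy). The negative log-likelihood is
non-increasing across EM iterations; convergence is a relative NLL change
below 1e-8 or 150 iterations. On noiseless exact-overlap data σ²
legitimately collapses to zero; this is reported as converged with a
`degenerate_variance` flag and a warning rather than an error.

**Fusion and cranial-base registration.** `fuse_dentition()` runs ICP on
the scan vertices against the CT vertices, then CPD seeded with the ICP
result; sets larger than `max_points` (default 600) are deterministically
subsampled (every k-th vertex) for CPD only, bounding the N×M posterior
matrix. `register_cranial_base()` restricts ICP to a vertex mask of at
least 100 vertices — the cranial base, which surgery does not expose — so
the recovered transform reflects imaging pose, never surgical
displacement.

`evaluate_case()` initialises the cranial-base ICP from a rigid
superposition of the landmarks shared by the two models. This exploits the
workflow's own structure — identical landmarks are reused on simulation
and postoperative models — and is what makes the evaluation invariant to
*arbitrary* re-posing of the postoperative model: the landmark fit removes
the pose to within the surgical displacement (a few mm/deg, inside ICP's
basin), and the masked surface ICP then converges on the cranial base.

## POSIT and NHP

The camera is an explicit pinhole: focal length in pixels (default 2000,
a portrait lens at ~1.5 m) and principal point, with u = u₀ + f·X/Z.
`posit_pose()` runs the classic POSIT iteration — solve the scaled
orthographic system through the pseudo-inverse of the reference-centred
model-point matrix, orthonormalise the two scaled rotation rows to a
proper rotation (via SVD projection), update the perspective corrections
εᵢ = (R₃·Pᵢ)/T_z, repeat until the corrections change by less than 1e-8
(cap 50) — and then polishes the pose with a Levenberg-damped Gauss–Newton
minimisation of the pixel reprojection error. The polish leaves noiseless
recovery at machine precision and brings the noisy estimate close to the
least-squares optimum; classic POSIT alone is exact without noise but is
not a least-squares estimator under noisy landmarks.
POSIT needs at least four corresponding landmarks and a non-coplanar model
configuration (centred condition number below 1e6); both are checked.

`reproduce_nhp()` applies **only the rotation** to the skeletal model —
the natural head position is an orientation; the camera-frame translation
is an artefact of where the photograph was taken and is discarded.

## Planning

The virtual osteotomy is a plane cut: vertices are split by signed
distance, crossing triangles are clipped (Sutherland–Hodgman per
triangle) and re-triangulated, and the boundary is left open — the sum of
the two output areas equals the input area. Capped cuts are deliberately
out of scope; segments are used for displacement and visualisation only.

A displacement step is either a translation along the anatomical axes or
a rotation defined by a center, a target point and a goal point. The
rotation is taken about the axis (target−center) × (goal−center) by the
angle between those directions: the *minimal* rotation carrying the
target direction onto the goal direction. The goal point therefore fixes
a direction, not a radius — distances to the center are preserved. This
is the natural reading when the defining points are an interface
convenience; a variant that also matched the goal's radius would not be a
rigid motion. Anti-parallel target/goal directions have no unique minimal
axis and raise an error.

`apply_plan()` applies steps in order (plan files are ordered;
translations conventionally precede rotations) and summarises the net
transform as six components: the net translation and the Euler
decomposition of the net rotation. When rotations are centred away from
the origin the summary translation is the net transform's translation,
which is the quantity the summary row of a displacement table reports.

The occlusal plane passes through the mesiobuccal cusps of the right and
left first molars and the central incisors; the "central incisors" point
is the `incisor_midpoint` landmark if present, else the midpoint of the
two central-incisor landmarks. Its frame takes x from right to left molar
cusp, z along the plane normal flipped into the +z hemisphere (ties
toward +y), y completing the right-handed triad. The frame is equivariant
under rigid rotations that keep the normal in the +z hemisphere — always
the case for occlusal planes of supine or upright subjects and for the
discrepancy magnitudes evaluated here.

## Evaluation and statistics

Linear discrepancy is signed, postoperative − simulation, per axis, with
per-landmark RMS √(dx²+dy²+dz²), evaluated at the eight maxillary tooth
landmarks. Angular discrepancy is the Euler decomposition of
F_post·F_simᵀ between occlusal frames. `recover_displacement()`
re-expresses the landmark superposition as a translation at the occlusal
centroid plus Euler angles, which is the six-component displacement the
synthetic generator applied — the end-to-end recovery target.

Summary tables use the sample SD (n−1 denominator) for both signed and
absolute values. The shipped 24-patient displacement table reproduces its
published signed mean ± SD row exactly at two decimals under this
convention. Two cells of the published absolute row do not recompute from
the published per-patient values: the absolute left–right mean (prints
1.16, recomputes 1.15) and the absolute SD row, which matches a
population (n) denominator instead (e.g. pitch 3.12 vs 3.18). Both are
treated as source rounding/convention inconsistencies; tests assert the
five absolute means that do recompute and the full signed row.

ANOVA is one-way (`aov`) on direction/orientation groups — a
repeated-measures design would also be defensible since the same patients
contribute to each direction, but the source analysis is not specified
beyond "ANOVA"; the limitation is noted. The post-hoc "different from the
other two" comparison is implemented as pairwise Welch t-tests with
Bonferroni correction (no post-hoc method is named in the source;
attribute `posthoc`). Pearson correlation uses `cor.test`'s two-sided t
test. The Kolmogorov–Smirnov normality check runs `ks.test` against a
normal with estimated mean and SD, without the Lilliefors correction —
the asymptotic p is anti-conservative with estimated parameters, a
documented caveat matching the source's bare "Kolmogorov–Smirnov test".
A zero-variance sample has no defined normality test and errors.

## Synthetic fixtures

No patient data ship with the package (the clinical CT/scan data behind
this workflow are restricted), so every input is emulated with known
ground truth:

* `make_skull_phantom()` — an ellipsoid cranium (semi-axes 55/65/45 mm)
  carrying smooth, seeded low-order asymmetric lobes (~6% radial
  amplitude) plus a parabolic dental-arch tube with Gaussian cusp bumps at
  eight tooth stations. The lobes matter: a clean ellipsoid has too much
  rotational symmetry for surface registration to lock, while
  high-frequency detail creates spurious ICP minima; smooth low-order
  asymmetry is what real crania provide. Landmarks come from a fixed
  template (facial set non-coplanar, pronasale offset anteriorly);
  regions (cranial base band, maxillary arch) are returned as index sets.
  Default resolution ~1400 vertices — enough for sub-0.01° registration
  recovery while keeping the full suite in seconds.
* `make_dentition_scan()` — extracts the arch submesh, drops 1−overlap of
  faces at random, adds Gaussian vertex noise, and moves the result by
  the *inverse* of the requested transform, so fusion must recover
  exactly that transform.
* `make_photo_projection()` — rotates the facial landmarks about their
  centroid, places them at the camera distance (default 1.5 m),
  perspective-projects, adds pixel noise. Points behind the camera error.
* `make_postop_case()` — displaces the maxilla region and dental
  landmarks by a six-component displacement (rotation about the occlusal
  centroid, then translation), optionally noises the cranial surface and
  re-poses everything rigidly. The exact per-landmark ground truth is
  returned alongside.

Each generator seeds its own offset RNG stream (and restores the caller's
state), so outputs are bit-reproducible per seed and adding one generator
never shifts another's stream. What the phantoms deliberately do **not**
model: CT metal artifacts (only missing/noisy regions stand in for them),
soft tissue, real dental morphology, segmentation error, or non-rigid
anatomy change between scans. Passing tests therefore demonstrate
correctness of the geometry and estimation machinery under the stated
noise models, not clinical accuracy on patient data.

## Numerical choices

Rotation validity is enforced at 1e-9 (orthonormality and determinant);
Euler round-trips are tested at 1e-9 degrees away from lock. STL files
are parsed in both binary and ASCII dialects with facet-soup vertices
merged at 1e-6 mm (STL stores facets independently; merging restores
connectivity; coordinates are float32 on disk). Plane cuts classify
vertices with an 1e-12 tolerance on signed distance. CPD declares
degenerate variance below 1e-12 mm². The CPD subsample cap (600 points)
and the phantom resolution (~1400 vertices) are the problem sizes used by
the tests and the acceptance script; both were chosen as the smallest
sizes at which the recovery oracles are comfortably exact, and scale up
directly for larger meshes.

## Interfaces

Landmark sets, photo landmarks, plans, transforms and reports are tibbles
or JSON/CSV files; results carry broom-style `tidy()`/`glance()` methods
and `autoplot()`/`plot_displacement_summary()` charts, so the natural
call pattern is pipe-based. Meshes and rigid transforms are light S3
objects — they are not tabular, and forcing them into data frames would
obscure the linear algebra. A thin command-line script
(`inst/cli/orthoflow`) exposes the workflow stages (`fuse`, `nhp`,
`plan-apply`, `evaluate`, `fixtures`, `summarize`, `run`) over the same
exported functions for file-based use.
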