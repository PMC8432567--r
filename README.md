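# orthoflow

Desk-scale R toolkit for the fully digital orthognathic-surgery workflow:
fusing optical dentition scans with CT skeletal models, reproducing the
natural head position (NHP) from a single facial photograph, rigid surgical
planning and simulation of bone segments, and 3D landmark-based evaluation
of surgical accuracy.

## Who it is for

Bimaxillary orthognathic surgery repositions the maxilla and mandible to
correct dentofacial deformity. Digital planning replaces plaster model
surgery: CT-derived skeletal meshes are fused with artifact-free optical
dentition scans, oriented into the patient's natural head position, cut and
displaced virtually, and — after surgery — compared against the
postoperative CT to quantify how faithfully the plan was executed. This
package implements each of those computational stages for engineers and
researchers who work with such pipelines, together with seeded synthetic
skull phantoms so every stage can be validated against known ground truth.

## The methods at its core

* **Dentition-CT fusion** — trimmed point-to-point ICP (k-d-tree
  nearest-neighbour correspondence, distance gating, worst-fraction
  trimming, SVD rigid fits) provides the initial match; rigid **coherent
  point drift** (EM over a Gaussian mixture with a uniform outlier
  component of weight *w*) refines it. Registration currency is the rigid
  transform *x → Rx + t* with *R* a proper rotation.
* **NHP reproduction** — the head rotation is estimated from ≥4
  non-coplanar facial landmarks (pronasale, bilateral exocanthion,
  endocanthion, cheilion) and their pixel positions in one photograph by
  **POSIT** (pose from orthography and scaling with iterations), polished
  by a Gauss–Newton reprojection fit; only the rotation is applied to the
  skeletal model.
* **Planning** — segments are translated along the left–right (x),
  advance–setback (y) and impaction–elongation (z) axes and rotated about a
  center by the angle between target and goal directions. The net transform
  is summarised as the six components (Δx, Δy, Δz, pitch, roll, yaw) under
  the fixed-axes convention R = R_z(yaw)·R_y(roll)·R_x(pitch).
* **Evaluation** — postoperative and simulation models are registered on
  the cranial base (surgically untouched), then per-landmark discrepancies
  d = postop − sim with RMS = √(dx²+dy²+dz²) are computed at the eight
  maxillary tooth landmarks, and the occlusal-plane orientation change is
  decomposed into pitch/roll/yaw. Summary statistics, one-way ANOVA,
  Pearson correlation and Kolmogorov–Smirnov normality checks round out the
  report.

## Worked example

```r
library(orthoflow)

# a seeded phantom: stylised skull with landmarks + a dentition scan taken
# at a known pose (2, -1.5, 3 deg / 2, -2, 1.5 mm off the CT frame)
ph   <- make_skull_phantom(phantom_spec(seed = 42))
scan <- make_dentition_scan(ph$mesh, ph$regions$dentition,
          rigid_transform(euler_compose(2, -1.5, 3), c(2, -2, 1.5)),
          noise_sd = 0.05, overlap = 0.8, seed = 42)

fuse_dentition(scan$mesh, ph$mesh)
#> <registration_result: fusion>  rms 0.085554 mm, 37 iterations, converged
#> <rigid_transform>
#>   translation (mm):   1.9987  -1.9967   1.5042
#>   rotation (deg)  : pitch  1.9951  roll -1.5250  yaw  2.9968
```

The fusion recovers the generating pose to a few hundredths of a mm/degree;
the 0.086 mm rms is the scan's own noise floor. Downstream, a synthetic
"postoperative" model whose maxilla was displaced by 0.61/0.86/1.00 mm and
1.43/0.50/0.58° (and then arbitrarily re-posed) evaluates to:

```r
po <- make_postop_case(ph$mesh, ph$landmarks, ph$regions$maxilla,
        applied = c(0.61, 0.86, 1.00, 1.43, 0.50, 0.58),
        global_pose = rigid_transform(euler_compose(5, -3, 8), c(12, -7, 9)),
        seed = 42)
report <- evaluate_case(ph$mesh, ph$landmarks, po$mesh, po$landmarks,
                        ph$regions$cranial)
report
#> <discrepancy_report>
#>   cranial-base registration rms: 0.0000 mm
#>   mean |dx| 0.638  |dy| 0.878  |dz| 0.914  rms 1.459 mm
#>   occlusal pitch 1.430  roll 0.500  yaw 0.580 deg
report$net
#> # A tibble: 1 x 6
#>   left_right advance_setback impaction_elongation pitch  roll   yaw
#> 1      0.610           0.860                 1.00  1.43 0.500 0.580
```

The cranial-base registration has removed the re-posing exactly (rms ~0),
the occlusal angles read back the applied rotation, and the recovered net
displacement matches the applied one. Per-landmark detail is available as
`tidy(report)`, a one-row summary as `glance(report)`, and
`autoplot(report)` draws the per-landmark discrepancy chart.

The package also ships the planned displacements of a published 24-patient
bimaxillary cohort; `summarize_displacements(bimax_displacements()[, -1])`
reproduces that table's summary rows (signed mean ± SD and absolute
mean ± SD per component).

## Command line

A thin CLI over the same functions lives at `inst/cli/orthoflow`
(subcommands `fuse`, `nhp`, `plan-apply`, `evaluate`, `fixtures`,
`summarize`, `run`), reading STL meshes, JSON landmark/plan files and
writing transforms, simulation STLs and CSV reports.

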