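# nasoplan

Computer-assisted planning of trans-nasal endoscopic surgical corridors on
segmented CT volumes.

Trans-nasal endoscopy reaches the skull base — for example the
pre-chiasmatic optic nerve inside the optic canal — through the nasal
cavity and the sphenoid bone.  Whether a rigid endoscopic microdrill can
actually get there depends on the animal's or patient's anatomy: the
corridor the drill sweeps must thread the confined surgical space without
ever touching tissue that may not be violated (orbits, cortex, vessels).
`nasoplan` answers that question exhaustively, for surgeons and lab teams
planning such approaches on manually segmented CT scans, and for anyone who
needs a deterministic, testable voxel collision engine for straight-tool
trajectory feasibility.

## The method

The input is a 3D integer label volume (NIfTI or NRRD) in which every voxel
carries one of four roles: **air** (outside the head), **surgical space**
(the permitted corridor volume), **non-surgical space** (forbidden tissue),
and the **surgical target** (e.g. the anterior wall of the optic canal).

The microdrill sweeping along its major axis traces a *surgical corridor*,
modeled as a capsule of radius r = d/2 (drill diameter d, hemispherical
tip) anchored with its tip at the target centroid **a** and extending
outward to the volume boundary.  A corridor pose has five degrees of
freedom

- rotations (rx, ry, rz) about the fixed world axes, composed as
  Rz·Ry·Rx and applied to the canonical outward (anterior) axis,
- spin about the corridor's own axis,
- travel `depth` along the axis (tip retraction from target contact),

discretized on a grid with steps and ranges (default 5° over 180° per
rotation, 5° over 360° of spin, 1 mm over 15 mm of travel), giving

```
(180/5) × (180/5) × (180/5) × (360/5) × (15/1) = 50,388,480
```

candidate poses.  A pose is **feasible** when every voxel center inside its
capsule is air, surgical space or target — equivalently, when no
non-surgical voxel center lies within r of the axis segment.  All poses
are tested; if none is feasible, the drill diameter is automatically
reduced in 0.5 mm steps and the search repeats until a path fits or a
floor diameter is reached.

Collision testing is exact: a clearance map (anisotropy-aware Euclidean
distance transform to the nearest forbidden voxel) prunes poses that are
certainly clear, and every ambiguous segment falls back to an explicit
local voxel test, so the accelerated check provably equals the brute-force
rasterized one on every pose.  Feasible paths are ranked by wall clearance
(minimal axis-to-forbidden distance minus r).

A seeded phantom generator builds analytic segmented "skulls" — a
13 mm goat-like trans-sphenoidal channel, a 2.5 mm macaque-like one, a
cortex-blocked variant and an orbit-flanked variant — so the whole planner
is testable without any CT download.

## Worked example

A conventional 2.9 mm endoscopic microdrill cannot pass a 2.5 mm-wide
sphenoid channel; the planner detects this and adapts the drill:

```r
library(nasoplan)

ph   <- generate_skull_phantom(phantom_preset("macaque"))   # 2.5 mm channel
grid <- search_grid(rot_step = 15, spin_step = 30, travel_step = 3)
res  <- adapt_tool_size(ph, tool_spec(2.9), grid)
res
#> <feasibility_result> drill 2.40 mm: 1,320 / 103,680 poses feasible (1.273%)
#>   adaptation trace (mm): 2.9 -> 2.4

glance(res)
#> # A tibble: 1 × 6
#>   tool_diameter_used n_poses_total n_feasible feasible_fraction n_adaptation_steps feasible
#> 1                2.4        103680       1320            0.0127                  2 TRUE
```

The search at 2.9 mm finds 0 of 103,680 poses feasible, steps the diameter
down by the 0.5 mm decrement, and at 2.4 mm finds 1,320 collision-free
corridors (1.3 % of the grid).  `rank_paths(res, ph)` orders them by
clearance, `autoplot(res)` maps the feasible approach directions, and
`export_path_mask()` writes the corridor union as an overlay volume for
inspection next to the CT.  On a goat-like 13 mm channel the same 2.9 mm
drill passes directly (7.7 % of poses feasible on the grid above).

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/nasoplan.R phantom --preset goat --out goat.nii.gz
Rscript inst/cli/nasoplan.R plan --input goat.nii.gz --output-dir out
Rscript inst/cli/nasoplan.R sweep --input goat.nii.gz --diameters 1.9,2.4,2.9 --out sweep.csv
```

`plan` exits 0 when a feasible path exists, 2 when the search ends
infeasible at the floor diameter, 1 on input errors.

## Scope

The package plans straight rigid-tool corridors on already-segmented label
volumes.  CT segmentation itself, curved or articulated trajectories,
DICOM handling and intraoperative navigation are out of scope; see the
methods vignette (`vignettes/corridor-planning.Rmd`) for the model's
assumptions, numerical conventions and limitations.
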