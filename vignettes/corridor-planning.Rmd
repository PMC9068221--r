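---
title: "Planning trans-nasal surgical corridors by exhaustive pose search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning trans-nasal surgical corridors by exhaustive pose search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasoplan)
```

## The planning problem

Trans-nasal endoscopic surgery reaches skull-base targets — here the
pre-chiasmatic optic nerve in its bony optic canal — through the nasal
cavity and sphenoid bone.  A rigid microdrill advanced along its own axis
sweeps a straight cylindrical volume, and the operation is possible only
if some orientation of that volume connects the target to the outside
world without crossing tissue that must not be touched: orbital contents,
cortex, vessels, or any other structure segmented as non-surgical.

`nasoplan` formalizes this as a feasibility search on a labeled CT volume.
Four voxel roles partition the scene: *air* (outside the head),
*surgical space* (the corridor volume the surgeon is permitted to open),
*non-surgical space* (forbidden), and the *target*.  Only non-surgical
voxels forbid passage; target voxels are allowed because the corridor
must touch the target by construction, and air is allowed because a
corridor may lawfully leave the skull.

### The corridor model

The drill is modeled as a capsule — a cylinder of radius $r = d/2$ with a
hemispherical cap, matching a diamond burr head — whose tip is anchored at
the centroid $\mathbf a$ of the target voxel centers.  A pose has five
degrees of freedom:

| parameter | meaning | default grid |
|---|---|---|
| $r_x, r_y, r_z$ | rotations (deg) about the fixed world axes | 5° steps over 180° each |
| spin | rotation (deg) about the corridor's own axis | 5° steps over 360° |
| depth | travel (mm) of the tip along the axis | 1 mm steps over 15 mm |

The corridor axis is $\mathbf u = R_z(r_z)\,R_y(r_y)\,R_x(r_x)\,
\mathbf{u}_0$, where $\mathbf u_0$ is the canonical outward direction
(anatomical anterior, $+y$, under the package's internal RAS convention):
the direction from the target out through the nose.  The tip sits at
$\mathbf a + \text{depth}\cdot\mathbf u$ and the capsule extends from the
tip along $\mathbf u$ to the exit of the volume's physical bounding box —
the whole shaft must be collision-free, not just the head.  Spin is
recorded because the full five-parameter grid defines the pose count, but
it cannot change the geometry of a circular cross-section; the search
exploits that (see *Determinism and caching*).

With the default grid this yields
$(180/5)^3 \times (360/5) \times (15/1) = 50{,}388{,}480$ candidate poses:

```{r}
n_poses(search_grid())
```

### Conventions that had to be fixed

Several discretization choices are not dictated by the problem and are
simply fixed, documented, and tested here:

* **Rotation composition** is extrinsic $R_z R_y R_x$ about the fixed
  world axes.  Any fixed order reproduces the same pose count; the order
  only relabels which triplet maps to which axis.
* **Angle grids are half-open and centered**: $r_\ast \in [-90°, +90°)$
  in steps of 5°, spin $\in [0°, 360°)$, depth $\in [0, 15)$ mm.  This is
  what makes 180/5 give exactly 36 values rather than 37, so the grid
  cardinality equals the closed-form product.
* **Depth retracts the tip** from target contact toward the entry
  (contact is depth 0).  A retracted corridor is the swept volume of a
  drill that stops short of the target.
* **Voxel-center membership** everywhere: a voxel belongs to a region —
  or to a capsule — iff its center does, with the *closed* convention
  that a forbidden center at distance exactly $r$ collides.  The
  voxel-center rule gives every geometric operation an exact brute-force
  oracle (scan all centers), which the test suite uses throughout.
* **Out-of-bounds space is air.**  The exterior of the scanned volume is
  not non-surgical tissue, so corridor segments beyond the volume cannot
  collide.  Poses whose *tip* leaves the volume are counted infeasible in
  a search (the target could not be reached from there under the model);
  the low-level corridor constructor can instead be asked to error.

## Collision testing: exact, twice

The reference rule is brute force: rasterize the capsule (all voxel
centers within $r$ of the axis segment) and test whether any rasterized
voxel is non-surgical.

The production path accelerates this with a *clearance map*: the exact
Euclidean distance transform (anisotropy-aware, in mm) from every voxel
center to the nearest forbidden center, computed by the
Felzenszwalb–Huttenlocher separable parabola algorithm in compiled code.
The corridor axis is sampled at half the smallest voxel pitch; around a
sample $p$ with nearest grid center $c$, the 1-Lipschitz bound
$f(p) \ge \text{cmap}(c) - \lVert p - c\rVert$ certifies whole segments
clear.  Wherever the bound cannot certify clearance, the checker falls
back to an explicit scan of the local voxel neighborhood large enough to
contain every center that could possibly be within $r$ of the segment,
evaluated with the same exact point-to-segment distance as the brute
force rule.  The fast check is therefore not an approximation: it must
and does return the identical verdict on every pose, which the test suite
asserts across phantom families, random scenes, and deliberate
distance-exactly-$r$ boundary cases.

Monotonicity properties pin the semantics down further and are tested as
invariants: growing the radius can only shrink the feasible set, adding
forbidden voxels can only shrink it, and mirroring the scene mirrors
feasibility corridor-by-corridor.  (The mirror property is checked at the
corridor level because the centered half-open angle grid is not closed
under reflection: $-(-90°) = +90°$ is not a grid value.)

## Drill-size adaptation and ranking

If no pose is feasible, the planner reduces the drill diameter by a fixed
decrement — 0.5 mm by default, the step between commercially adjacent
burr sizes — and repeats the whole search, down to a floor diameter
(default 1 mm, below which a drill is no longer a practical
bone-removal tool).  The result carries the full trace of attempted
diameters.  On a straight channel of width $w$ this recovers $w$: the
first feasible diameter lands within one decrement plus one voxel of the
channel width, which the acceptance tests verify for channels of 1.5,
2.5, 5 and 13 mm.

The underlying program's notion of "most feasible" paths is not
specified beyond feasibility itself, so ranking is this package's own
addition and is kept transparent: feasible poses are ordered by
decreasing *clearance* — the minimal distance from the axis segment to
any forbidden voxel center minus $r$, i.e. the margin in mm before the
corridor would graze tissue — with ties broken by smaller angular
deviation from the canonical approach axis, then lexicographic pose
order.  Clearance is computed exactly against the surface voxels of the
forbidden region (an interior forbidden voxel can only be nearest to a
corridor that is already inside the region, which a feasible corridor at
practical drill radii never is).

## Determinism and caching

Planning is bit-for-bit deterministic: pose enumeration is lexicographic
in $(r_x, r_y, r_z, \text{spin}, \text{depth})$, feasible-pose lists are
emitted in that order, reports carry no timestamps, and repeated runs of
the same configuration produce byte-identical JSON.  For circular tools
the collision verdict is computed once per unique
$(r_x, r_y, r_z, \text{depth})$ geometry and replicated across spin — a
pure-speed optimization that the tests show changes no count and no pose,
by running the search with caching disabled.

## The phantom generator

Real segmented CTs are large, private, and unnecessary for validating the
geometry, so the package generates analytic label volumes that emulate
the planning-relevant anatomy of a segmented skull:

* a solid **non-surgical block** spanning the volume — the sphenoid bone
  mass — pierced along the anterior axis by an open **channel** of
  parametric width (the trans-sphenoidal corridor);
* a **target slab** at the channel's posterior end, whose centroid
  anchors the search;
* a **posterior bone compartment** behind the block enclosing a blind,
  channel-coaxial **recess** behind the target.  The recess gives the
  capsule's hemispherical tip room at target contact; the surrounding
  bone closes the back of the scene so no corridor can exit through the
  posterior face of the volume.  (An earlier layout with open air behind
  the target let geometrically valid but anatomically absurd
  backward-exiting corridors count as feasible — the posterior skull is
  not an entry route.)
* an anterior air **vestibule**, optionally populated with obstacle
  bodies: an orbit-like lateral pair, or a slab fully crossing the
  corridor the way the frontal cortex blocks the approach in some
  species.

Four presets mirror the species contrasts that motivate the planner:
`"goat"` (13 mm channel at 0.65 mm voxels — the permissive anatomy),
`"macaque"` (2.5 mm channel — too narrow for a conventional 2.9 mm
drill), `"blocked"`, and `"orbit"`.  Everything is classified by
closed-form voxel-center membership, so each fixture has an exact
geometric oracle; optional seeded jitter roughens the channel wall after
classification (differences between seeds are confined to the boundary
band, which is itself a test).

Two generator choices deserve justification:

* **Macaque-like voxel size.**  The feasibility phase transition on a
  discrete channel is inherently about two voxels wide: a drill within
  one voxel of the channel width may or may not fit depending on where
  voxel centers fall.  The macaque contrast — 2.9 mm drill versus 2.5 mm
  channel — is a 0.4 mm interference, unresolvable at the 1 mm slice
  thickness of the source modality.  The macaque-like phantom is
  therefore sampled at 0.25 mm so that the discrete channel faithfully
  realizes its nominal width; this models the anatomy, not the scanner.
  The channel axis is placed on the cross-section's physical center,
  which for even grid dimensions falls midway between voxel centers and
  keeps the discretized wall symmetric (the first forbidden center sits
  half a voxel beyond the nominal wall).
* **Width verification.**  `measure_channel_width()` measures the
  inscribed-disc diameter at mid-channel from the in-plane distance
  transform, plus one in-plane voxel to compensate the half-voxel
  beyond-surface position of the nearest forbidden centers; across the
  1.5–13 mm fixture series this recovers the nominal width to within one
  voxel.

What the phantoms deliberately do **not** emulate: curved or branching
corridors, graded bone density (labels are categorical), segmentation
noise beyond wall jitter, and partial-volume effects at tissue
interfaces.  Passing tests on phantoms therefore validate the geometry
and search machinery, not the quality of any particular manual
segmentation; on real data the plan is only as good as the masks.

## Input handling

Volumes are read from NIfTI (via RNifti) or NRRD (a small built-in reader
for integer label volumes with axis-aligned space directions; raw, gzip
and ascii encodings).  Files are reoriented to the canonical RAS axes
when their header declares an axis-aligned orientation; oblique
acquisitions are rejected rather than silently sheared.  Label values
outside the declared scheme, non-integer data, and missing or zero
spacing are errors.

CT stacks are usually anisotropic (coarser slice spacing than in-plane
pixel size).  Whether the original planning program resampled its inputs
is unknown, so resampling is this package's own choice: metric capsule
geometry under rotation is only meaningful on an isotropic grid, so
`run_plan()` resamples nearest-neighbor (labels stay categorical) to the
smallest input spacing by default.  Per-label physical volume is
preserved within 5 % for structures a few voxels thick, which the tests
check on an anisotropic fixture.

## Problem sizes and runtime

The shipped tests and the acceptance script size their searches so the
full suite runs in well under a minute of compute: coarse grids of
$10^2$–$10^5$ poses for oracle-equivalence sweeps (where every pose is
checked twice, once per method), $\sim 10^5$-pose grids on the
$\le 104^3$ preset phantoms for the species contrasts, and a complete
plan — load, adapt, rank, report, overlay — on a $96^3$ phantom with a
15° grid (622,080 poses) as the end-to-end check.  The full 50-million
pose default grid reduces, after spin collapsing, to 699,840 unique
geometries and is within reach of the same machinery on real volumes; it
is not exercised in the tests because the coarse grids already determine
every verdict the fine grid could change only quantitatively.

## Limitations

* Straight rigid corridors only; no curved, articulated or multi-segment
  trajectories, and no tool cross-sections other than circular (spin is
  the extension point for that).
* Feasibility is purely geometric: no drilling mechanics, no soft-tissue
  deformation, no uncertainty in the segmentation.  A clearance-ranked
  path is a geometric suggestion, not a surgical judgment.
* The anchor is the target centroid; planning to an extended target
  surface patch-by-patch would require one search per anchor.
* The exterior-is-air rule means a volume cropped too tightly around the
  anatomy can let corridors exit through regions a wider scan would have
  shown to be tissue; crop generously.
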