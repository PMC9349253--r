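---
title: "Target-hit sectioning: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-hit sectioning: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planecut)
```

`planecut` plans cryostat sectioning so that one section hits the centers of
several targets embedded in a tissue block. This vignette is the package's
account of the underlying geometry, the statistical validation arithmetic,
the synthetic phantoms used to test everything, and the design decisions
taken where more than one convention was defensible.

## Coordinate frame and sign convention

A fiducial positioning plate inset in the block anchors the frame: the plate
border is the X-axis, the perpendicular through the plate end (the origin)
is the Y-axis, and the cutting-forward (specimen feed) direction is the
Z-axis. Because the block is reverted and its bottom face cut first, depth
`z_um` is measured from the face that meets the blade first.

Coordinates are stored as **positive magnitudes**. In the physical
convention the axes point away from the cut face, so written coordinates are
negative; keeping magnitudes in the data and the direction in the frame
avoids double-negation bugs, and every interface documents the axis
directions. Bottom-first cutting flips section images mirror-style about the
plate axis; `mirror_x()` implements that reflection (X negated through the
origin, Y and Z preserved) and is an involution, so registering a mirrored
observation applies the same map again.

## Plane construction

Given target centers, the *expected sectioning plane* is the plane through
them (`plane_through_targets()` for exactly three, `fit_plane()` —
orthogonal least squares via SVD — for more). With `Zb` the maximal target
depth, the plane raised by `Zb` (the *suppositional plane*) meets the bottom
face at the deepest target's footprint; raised by `2 Zb` it becomes the
*virtual sectioning plane*, realized by needles of height `2 Zb - Zi` at
each footprint on a dummy block. The three planes are parallel with equal
spacing, and because `Zb` is the maximum depth, every needle height is
nonnegative; when several targets tie for deepest the first in input order
is labelled the reference, which cannot change the heights since only the
value of `Zb` enters the formula.

### Advance bookkeeping

The cryostat advances the specimen in fixed-thickness steps along the feed
axis, so cutting-forward distances are measured **along Z**, not along the
plane normal: the advance that carries the blade plane through a marked
bottom point equals the point's plane distance divided by `cos(tilt)`. All
advances in this package are referenced to the **virtual-plane start
position** (the blade as aligned on the needle tips): the advance to the
deepest target's bottom mark is then exactly `Zb`, and the advance to the
expected plane — where every target center lies on the blade — is `2 Zb`.
The physical protocol re-zeroes its distance counter in ways that cannot be
reconstructed from the block geometry alone (the recorded validation
distances are on the scale of `Zb`, not `2 Zb`), so the virtual-plane
reference is a package convention; it is self-consistent across the planner,
the simulator and the tests.

### Feasibility

The instrument can only be set to a limited angle between blade and block
face; the default capacity is 20° and is exposed as a parameter because it
is instrument-specific (holders in routine use quote ranges such as 15–20°).
A tilt exactly at capacity is feasible (the capacity is quoted as a closed
range). Infeasible planes are reported with the suggested pre-trim wedge
angle `tilt - capacity`: trimming an inclined face by that wedge before
mounting brings the residual tilt within capacity — e.g. a 29° plane becomes
cuttable after a 9° wedge (equivalently, trimming the back at 81° to the
bottom).

## Sectioning schedules and the simulator

Two schedules cover the protocol:

* `plan_schedule(expected, trim = 20, fine = 7, margin = 1000)` — 20 µm
  trims until 1000 µm before the expected position, then 7 µm fine sections;
  the plan extends one margin past the expected position so the target is
  bracketed. The trim count is `floor((expected - margin)/trim)`.
* `plan_serial_survey(height, fine = 7, interval = 100)` — the localization
  survey: one collected 7 µm section per 100 µm of advance,
  `floor(height/interval)` sections in total. Collected mid-planes are
  spaced exactly one interval apart (whether the interval is counted from
  section start or end is not observable at this scale; the mid-plane
  convention is used).

`simulate_cut()` evaluates each collected section at its **mid-plane**: a
spherical target of radius `r` is present iff the unsigned center-to-plane
distance `d` is below `r`; the reported centroid is the orthogonal
projection of the center onto the plane and the cross-section radius is
`sqrt(r^2 - d^2)`. A 7 µm slab is thin relative to the targets, so slab
integration is deliberately avoided. Sections are numbered 1-based in
advance order, as histologists count them.

## Localization

`estimate_centers()` averages the per-section centroid coordinates per axis
(the Z estimate averages the mid-plane advances) over all sections where the
target is present, **unweighted** — sections near the sphere's edge count as
much as central ones. For symmetric sampling of the presence interval the
mean is unbiased; the survey's fixed phase can bias Z by up to half an
interval, which is within the measurement quantization and far below target
radii. Measurements are quantized at reading time (`quantize_measurement()`,
nearest 100 µm with ties away from zero), emulating coordinates read off
grid paper; averaging happens after quantization, as in the manual
procedure.

## Validation statistics

The repeatability arithmetic reproduces the phantom-study tables:

* `cv()` — sample standard deviation (`n - 1` denominator) of the
  measurement magnitudes divided by the absolute mean. The `n - 1`
  convention is not stated with the reference tables but reproduces every
  printed per-coordinate and per-target CV; the `n` denominator does not.
* `total_cv()` — the unweighted mean of component CVs, verified against both
  printed totals (0.03134 for the nine position CVs, 0.068 for the three
  actual-distance CVs).
* `pearson_r()` — product-moment correlation of the pooled (foreknown,
  measured) pairs, n = 36.
* `paired_t()` — Student's paired t on the 12 (actual, expected) distance
  pairs; mean difference 119 µm, t = 1.389, df = 11, two-tailed p = 0.1924.

One reproduction limit is worth recording: the correlation computed from the
rounded reference-table values is 0.9986812, while the figure accompanying
the study reports 0.998699. No sign convention, alternative pooling, or
single-entry perturbation of the table recovers the reported value, so it
was presumably computed on unrounded raw measurements; the package reports
the value its inputs actually produce. Tukey multiple comparisons quoted
alongside the tables are an off-the-shelf procedure (`TukeyHSD()` in base R)
and are not re-derived here.

## Synthetic phantoms

`three_target_model()` is the reference phantom: Red (2000, 1000, 4000),
Green (8000, 3000, 5000), Blue (5000, 7000, 6000) µm in a 10 × 8 × 8 mm
frame. The target radius defaults to 500 µm — the physical models' target
size is not recorded, and 500 µm makes a 100 µm survey yield ~10 positive
sections per target, matching how many sections per target the manual
procedure averages. `random_block()` draws seeded random target sets,
rejecting near-collinear triples (minimum point-to-line distance 300 µm) so
planes are well conditioned. `organ_preset()` carries the three organ-scale
frames (aortic root 6 × 6 × 5 mm with three valve targets, orbit
12 × 8 × 6 mm and thorax 25 × 25 × 17 mm with two targets each); the target
placements are plausible synthetic geometry, not anatomical measurements.
`add_measurement_noise()` models the manual readout: Gaussian in-plane
jitter (default SD 50 µm, reproducing the 0–200 µm deviations seen in the
reference measurements) followed by quantization to the 100 µm grid; the
advance readout is quantized without jitter.

What the phantoms deliberately do **not** model: section compression,
tearing, tape transfer, knife marks, stain variability, registration error
beyond the jitter term, and non-spherical target shapes. Passing tests
therefore demonstrate the geometry and the statistical pipeline, not
robustness to histological artefacts.

## Numerical choices

Absolute tolerance 1e-6 µm for geometric predicates; unit normals to 1e-9;
plane normals oriented with positive Z component (vertical planes are
rejected — a 90° cut is physically meaningless here). Lengths are µm and
angles degrees at every interface; radians appear only internally.
Degenerate inputs fail loudly: collinear targets name the offending targets,
zero-variance differences refuse the paired test, a zero mean refuses the
CV.

## Problem sizes

The property suites run 200 seeded random blocks for the noiseless plane-hit
invariant (every target center within half a section thickness, 3.5 µm, of
the blade at the planned advance) and 100 seeded full-pipeline replicates
under measurement noise (success = one simulated section containing all
three targets; observed rate 100%, required ≥ 95%). These sizes give stable
rates while keeping the default test run fast on a laptop.

## Known limitations

* Planning assumes the data-in block is geometrically identical to the
  data-out block; biological pairing error between specimens is out of
  scope.
* The advance reference is the virtual-plane start (see above); distances
  recorded by instruments with a different counter zero must be shifted
  before comparison.
* Only spherical targets are simulated; elongated structures are handled in
  practice by planning on their endpoint targets.
* Organ presets are geometry fixtures; no organ-level numeric claims are
  made.
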