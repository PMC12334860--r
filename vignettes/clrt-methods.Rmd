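---
title: "Converging-lens treatment planning: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converging-lens treatment planning: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the dose model and its assumptions, the planning algorithm, the tunable
parameters, and the places where the design was genuinely open and a
choice had to be made.

## The modality

Converging-lens radiotherapy (CLRT) focuses a quasi-monoenergetic ~60 keV
x-ray beam through a lens onto a small focal volume. Unlike a diverging
Linac beam, the radiation arrives through a *hollow convergent cone*: the
entrance dose is spread over a conical shell and concentrates into a
pronounced peak at the focus. Mounted on a robotic arm, the source can
approach from essentially any direction, limited mainly by the
water-equivalent depth of the target (about 80 mm in normal tissue,
deeper through lung). Treatment planning therefore looks less like
fluence-map optimization and more like spot placement: many focal "shots"
(target point + direction) whose non-negative weights are optimized
jointly.

## Dose kernel

The package uses a parametric analytic kernel per unit beam weight, the
sum of two components.

**Focal volume.** An anisotropic Gaussian aligned with the beam axis,
with the lens's nominal lateral and longitudinal FWHMs in water
(`builtin_lens("A")`: 22.5 mm longitudinal × 3.4 mm lateral;
`builtin_lens("B")`: 10.8 × 1.3 mm), peak normalized to 1 at the focus
and truncated at 5σ for sparsity. The truncation discards
< 4·10⁻⁶ of the peak and keeps the dose-influence matrix sparse.

**Cone shell.** For voxels upstream of the focus whose polar angle from
the beam axis lies between the inner and outer cone half-angles (defaults
20° and 25°), the dose is

    entrance_level × (r_entry / max(r, r_floor)) × exp(−μ · z_rad)

where `entrance_level = 1/peak_to_entrance_ratio` (default ratio 20),
`r` is the distance to the focus, `r_entry` the distance from the focus
to the body-entry point along the ray through the voxel, and `z_rad` the
radiological depth from that entry to the voxel. The factor
`r_entry/max(r, r_floor)` models the concentration of photon fluence as
the annular shell shrinks toward the focus; it is normalized to 1 at the
entry point, and capped at `r_floor` = the longitudinal FWHM, roughly
where the shell merges into the focal Gaussian. Attenuation uses
`μ_water = 0.0206 /mm` (the linear attenuation coefficient of water near
60 keV) applied to the *water-equivalent* depth, so heterogeneity enters
through density only — a deliberate simplification appropriate for a
planning-level model.

There is no cone contribution downstream of the focus, dose is exactly
zero outside the BODY mask, and the kernel is linear in weight by
construction (weights enter only in the accumulation step).

Assumptions worth keeping in mind: no scatter transport, no spectral
polychromaticity, and no photoelectric dose enhancement in bone (a real
60 keV beam deposits noticeably more dose in cortical bone than this
density-scaled model predicts). The cone half-angles, entrance-dose level
and source-focus distance of the physical treatment head are not public;
the defaults above are stated conventions, each overridable in
`lens_spec()`.

## Ray tracing

Radiological path lengths use exact interval-walking voxel traversal
(Siddon-style): the sum over traversed voxels of geometric intersection
length × density, with mass density in g/cc used directly as the
water-equivalence factor (a good approximation near 60 keV for soft
tissues; it under-weights cortical bone attenuation). Exact traversal
rather than fixed-step sampling makes path additivity hold to 10⁻⁶ mm,
which the test suite exploits. `depth_to_point()` finds the *outermost*
body crossing along the reversed beam direction, so air gaps and
re-entrant surfaces are handled by integrating density (≈ 0 in air) from
the outside in.

## Planning algorithm

1. **Target sampling.** A cubic lattice of pitch
   `spacing_factor × lateral FWHM` anchored at the PTV centroid, clipped
   to the PTV, with a centroid fallback for sub-pitch targets.
   `spacing_factor` defaults to 1.2 — "slightly wider than the lateral
   FWHM", so that neighbouring focal volumes tile the target with a small
   controlled ripple rather than heavy overlap.
2. **Approach regions.** 256 candidate directions per point on a
   deterministic Fibonacci sphere lattice; a candidate is feasible when a
   body entry exists and the water-equivalent depth of the point does not
   exceed the lens depth limit (80 mm default). Only the depth criterion
   gates feasibility; the robot's mechanical clearance envelope is not
   modelled, because no public description of it exists.
3. **Direction assignment.** The feasible set is partitioned into
   `n_segments` (default 5) groups of near-equal size by seeded k-means
   on the unit vectors (the chordal metric on the sphere), and the member
   closest to each group centroid is chosen, ties broken by lowest
   candidate index. This realizes "one direction from each of several
   equal segments" with a standard, reproducible algorithm.
4. **Weight optimization.** See below.
5. **Accumulation and evaluation.** Final dose `d = D w`, DVHs, indices.

Determinism: every stage is deterministic given the config seed (the seed
reaches the k-means initialization and the phantom noise texture;
everything else is closed-form). Re-running a pipeline with the same seed
produces byte-identical plan files.

## Objective, constraints and optimizer

Objectives are one-sided quadratics per structure: the mean over the
structure's voxels of the squared deviation from the prescribed dose,
counted only on the under- (or over-) dosed side. The Heaviside gate uses
the convention Θ(0) = 0, so a voxel exactly at prescription contributes
nothing from either side — immaterial for the value (the quadratic
vanishes there anyway) but stated for determinism. Objectives are
combined as a penalty-weighted sum; hard max/mean-dose constraints are
folded in as quadratic penalty terms with a single fixed multiplier
(default 10⁴), and residual violations are reported on the plan rather
than silently absorbed. A growing multiplier schedule was rejected
because it would break the monotone objective-trace contract at stage
boundaries.

The solver is a monotone **spectral projected gradient** method:
Barzilai–Borwein step lengths, Armijo backtracking, and projection onto
`w ≥ 0`, started from uniform weights scaled so the mean PTV dose equals
the prescription. For this piecewise-quadratic convex objective the
method is simple, robust, and — because only accepted (strictly
decreasing) iterates enter the trace — yields a per-iteration objective
trace that is non-increasing by construction, which a quasi-Newton
line-search solver behind `optim()` cannot expose. Convergence is
declared at relative objective change below `tol` (default 10⁻⁶, at most
`max_iter` = 500 iterations).

Default penalties (PTV underdose 1000, PTV overdose 500, BODY overdose at
prescription 10) encode the usual clinical asymmetry: target coverage
matters more than target homogeneity, and prescription-level dose outside
the target is discouraged everywhere.

## Evaluation conventions

* DVHs are cumulative ("volume receiving at least"), threshold rule `≥`,
  default bin width 0.1% of prescription.
* `Vx` uses the inclusive `≥` rule too, stated for bit-reproducibility.
* In CI's denominator, V100 is taken over the **whole grid**, not
  restricted to BODY — the standard conformity-index definition.
* GI is 50% divided by the difference of the equivalent-sphere radii of
  the 50% and 100% isodose volumes, in %/cm; coincident radii report
  `Inf`.

A consequence of the inclusive threshold: at a *converged* optimum the
PTV voxels sit numerically at the prescription, some a hair below, so
TCI can read well under 1 even when every voxel is within a fraction of
a percent of the prescribed dose. TCI should therefore be read together
with the DVH (or the ±10% coverage fraction), not alone.

## What the synthetic phantoms do and do not emulate

The phantom factory produces water bodies with optional bone shells
(1.85 g/cc), lung blocks (0.26 g/cc) or a bone cylinder, a spherical PTV
and one offset OAR sphere, plus a mild seeded density texture
(σ = 0.02 g/cc) that stands in for CT noise. Masks are binary,
full-resolution, center-in-structure rasters. These phantoms exercise
every code path (heterogeneous attenuation, depth feasibility,
OAR-constrained optimization) but are *not* anthropomorphic: no realistic
organ shapes, no motion, no HU calibration curve beyond the stated
piecewise-linear convention (−1000 HU → 0.001, 0 → 1.0,
1000 → 1.6 g/cc, clamped). Passing tests on these phantoms demonstrates
algorithmic correctness, not clinical dosimetric accuracy on patient
CTs.

The default end-to-end scenario mirrors a small deep-seated cranial
metastasis: a 60³ grid at 2 mm spacing (a typical clinical dose-grid
resolution), a spherical target of analytic volume 0.36 cc prescribed
27 Gy in 5 fractions, planned with Lens B. At this resolution the
problem has more beams (585) than PTV voxels (56) and the optimizer
drives the objective to numerical zero; on a 1 mm grid the same scenario
leaves a few percent of edge voxels outside ±10% of prescription — the
five-directions-per-point angular budget, not the optimizer, is the
binding constraint there, which is the same trade the physical system
faces ("segments limited by computing power").

Numerical problem sizes throughout the test suite (grids of 30³–100³
voxels, 0.25 mm profile grids, a few hundred beams) were chosen so the
full suite exercises every module in a few tens of seconds on one CPU
while keeping discretization errors well inside the asserted tolerances.

## Degenerate inputs and edge cases

* Empty PTV, PTV outside BODY, beam targets outside BODY, unknown
  structure labels and malformed configs fail fast with typed conditions
  (`clrt_invalid_geometry`, `clrt_config_error`, ...).
* A target point deeper than the depth limit from every direction raises
  `clrt_unreachable_target` at assignment; the pipeline skips such points
  and fails only if *no* point is deliverable.
* Profiles that never fall below half maximum within the grid raise
  `clrt_profile_unresolved` instead of extrapolating.
* `max_iter = 0` returns the scaled initial weights with a length-1
  trace; all-zero penalties are rejected as degenerate.
* Dose-influence entries below 10⁻⁶ of their column maximum are dropped;
  with the 5σ Gaussian truncation this bounds the sparsity error far
  below the optimization tolerance.

## Known limitations

* The kernel is a planning-level analytic surrogate: no Monte Carlo
  transport, no scatter tails, no bone photoelectric enhancement.
* Approach-region feasibility ignores collision/clearance geometry.
* DVH-based objectives, robust/4D optimization and adaptive re-planning
  are out of scope.
* NRRD support covers the subset the package writes (3-D scalar volumes,
  raw/ascii/gzip encodings, little-endian); DICOM is not supported.
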