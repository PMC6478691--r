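---
title: "Lung lymphatic morphometry and coupled Stokes-Darcy microfluidics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung lymphatic morphometry and coupled Stokes-Darcy microfluidics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Pulmonary lymphatics drain interstitial fluid toward the pleural surface;
their three-dimensional arrangement in peripheral human lung is poorly
characterised, and imaging them requires combining lymphatic-specific
immunohistochemistry with high-resolution micro-CT of paraffin-embedded
tissue.  `pulmolymph` reimplements, at desk scale, the two computational
halves of such a study:

1. **3D morphometry** of a labelled voxel volume: random region-of-interest
   (ROI) sampling, subpleural/intralobular classification by Euclidean
   distance to the pleural surface, and six per-VOI measures of the
   lymphatic network (volume fraction, surface area per tissue volume,
   box-counting fractal dimension, branch count, junction count, mean
   branch tortuosity), with nonparametric group comparison and distance
   regression.

2. **Steady microfluidic modelling**: Darcy flow in the interstitium,
   Stokes flow in the blood and lymphatic lumens, and a
   hydraulic-conductivity membrane condition on every vessel wall, solved
   on the voxel grid with the literature parameter set, plus the x100
   parameter-sensitivity protocol judged against a grid-refinement
   estimate of the discretisation error.

Because the study's segmented patient volumes are cluster-scale and not
redistributable, a **synthetic volume generator** stands in for the
segmentation.  Its outputs are first-class, tested objects with known
ground truth, which is what makes parameter-recovery tests possible.

# The flow model

With `p` the interstitial pressure (Pa), `u` the fluid flux (m/s), `k` the
interstitial permeability and `mu` the viscosity:

* interstitium (Darcy, incompressible):
  `u = -(k/mu) grad p`, `div u = 0`;
* vessel lumens (creeping flow, blood `B` and lymph `L`):
  `0 = mu lap(u^i) - grad p^i`, `div u^i = 0`;
* every internal vessel-interstitium face (membrane):
  `u^i . n = K^i (p^i - p)`, with `K^i` the wall hydraulic conductivity
  (m s^-1 Pa^-1) and `n` the outward lumen normal; the tangential velocity
  at membrane faces is zero (the model does not state a tangential slip,
  and no-slip is the conservative completion);
* boundary conditions: Dirichlet pressure on all external interstitial
  faces; prescribed uniform normal inlet velocity on the vessel openings
  of the three cube faces furthest from the pleura; Dirichlet outlet
  pressure on the remaining vessel openings, with backflow suppression;
  no-flux/no-slip on every air-adjacent face; gravity neglected.

Default parameters (all overridable through `fluid_parameters()`):

| symbol | value    | units           | meaning                          |
|--------|----------|-----------------|----------------------------------|
| mu     | 1.2e-3   | Pa s            | fluid dynamic viscosity          |
| rho    | 1030     | kg m^-3         | fluid density (carried only)     |
| k      | 4.4e-18  | m^2             | interstitial permeability        |
| phi    | 0.13     | --              | interstitial porosity            |
| p      | -1064    | Pa              | external interstitial pressure   |
| u^L    | 3e-4     | m s^-1          | lymphatic inlet velocity         |
| p^L    | -1200    | Pa              | lymphatic outlet pressure        |
| K^L    | 1.9e-12  | m s^-1 Pa^-1    | lymphatic wall conductivity      |
| u^B    | 3e-3     | m s^-1          | blood inlet velocity             |
| p^B    | +2000    | Pa              | blood outlet pressure            |
| K^B    | 2.71e-12 | m s^-1 Pa^-1    | blood wall conductivity          |

Porosity `phi` does not appear in the steady equations above; it is
carried so the pore (seepage) velocity `u/phi` can be derived, and because
the parameter set treats it as part of the tissue description.  The
density never enters a steady incompressible model without gravity.

## Discretisation

The solver works directly on the voxel grid with a marker-and-cell
(staggered) finite-volume scheme: one pressure unknown per fluid cell and
one normal-velocity unknown per lumen-lumen face.  This replaces the
commercial tetrahedral meshing + finite-element stages of the original
workflow while keeping the mathematical model; the cost is a staircase
representation of curved walls, which is why every oracle below is also
run under grid refinement.

Every pressure-coupled face carries an affine velocity
`u = cst + c_lo p(lo) + c_hi p(hi)`:

* interstitial faces: `c = k/(mu h)` (the two-point Darcy flux);
* membrane faces: `c = K^i` (the membrane law written per face);
* external Dirichlet faces: `c = 2k/(mu h)` (half-cell ghost);
* inlet faces: a constant.

Continuity of any fluid cell sums these face velocities, so Darcy cells,
lumen cells and membrane coupling all assemble through one code path.
Lumen momentum uses the standard staggered 7-point viscous stencil with
no-slip ghosts (`u_ghost = -u`) across walls, algebraic substitution of
membrane/inlet neighbour faces, and a one-sided (fully developed) normal
derivative at outlet faces, where the pressure gradient uses the
prescribed outlet pressure at the face.  Outlet faces showing inward flow
after a solve are converted to sealed walls and the system re-solved, up
to 20 passes; a class with no inlet keeps its least-backflowing outlet
face as pressure reference and the result is flagged instead.

## Linear solver

The assembled matrix mixes pressures (~1e3 Pa) and velocities (~1e-9 m/s),
so convergence is always measured with the componentwise backward error
`max_i |r_i| / (|A||x| + |b|)_i`, which protects the tiny interstitial
continuity rows from being declared converged by a global norm.  Small
systems use a sparse LU after row/column equilibration with iterative
refinement.  Larger systems exploit the block structure: the interstitial
pressure block is symmetric positive definite and factored once with a
supernodal Cholesky; the (much smaller) lumen block is factored once with
a sparse LU; the two are alternated in correction form (block relaxation
on the residual) through the weak membrane coupling.  With the default
conductivities the coupling ratio is ~1e-2 and the iteration converges in
a handful of sweeps; at `K x100` it remains below 1.  Mass-balance
defects per domain close to ~1e-11 relative on the coupled VOI runs and
to machine precision on the 1D oracles.

## Problem sizes

All shipped analyses and tests run at desk scale: flow VOIs are 32^3 to
40^3 voxels at 13.2 um pitch (420-530 um cubes), with one-step grid
refinement to 64^3/80^3 for the discretisation-error estimates, and
morphometry sections up to 44 x 320 x 970 voxels.  These sizes keep every
stage within minutes on one CPU while leaving at least ~8 voxels across
each lumen diameter for the larger vessels and >= 3 box-counting decades
for the fractal fits.

# The synthetic generator

`generate_voi()` emulates what a segmented peripheral-lung volume looks
like to the downstream code, not how lung grows:

* a 2-voxel **pleural shell** on one declared face;
* a **blood-vessel tree** built from random recursive centreline polylines
  rasterised with spherical brushes (root radius 40 um, taper 0.75),
  connecting the requested per-face openings through a central hub, with
  supply openings placed on the deep half of lateral faces and drainage
  openings on the shallow half (vessels course pleura-ward);
* **alveolar airspaces**: overlapping spheres (radius 65-105 um, alveolar
  scale) carved to a target air fraction (default 0.45), clipped at the
  volume boundary like a real VOI, leaving 1-3-voxel septa;
* a **connected lymphatic network**: entry stubs at the requested
  openings, a backbone spanning the depth axis (drainage is pleura-ward),
  thin bridge threads joining extra stubs to the backbone, lateral
  collector lines in wide volumes, and depth-bin-targeted sprouts that
  always start on existing lymph.  Tubular sprouts grow *geodesically*: a
  BFS distance field from the current network through the interior tissue
  of the bin's depth slab (padded when alveoli disconnect a thin slab),
  with each new segment walking downhill back to the network -- connected
  by construction and threading the septa around airspaces the way real
  lymphatics do.  A configurable fraction of segments is rendered as
  1-voxel-thick sheets (the partially collapsed morphology that stresses
  skeletonisation and box counting), a fraction is routed perivascularly,
  and one ring fully encircling a blood vessel is laid in a single slice
  (verifiable by 2D flood fill);
* the lymphatic volume fraction follows `vf(d) = vf0 + g d` per ~110 um
  depth bin, with exact voxel budgeting (sprouts are truncated along
  their path when a bin's budget is reached; slab traversals through
  on-budget bins keep only their centreline thread), so the realized
  per-bin fraction sits within a few percent of the model and always
  inside the +-20% contract.

Everything is derived from one seeded stream, so identical specs give
bitwise-identical volumes; cohorts derive one sub-seed per volume.

What the generator does **not** emulate: micro-CT physics (noise, beam
hardening), stain rendering, registration artefacts, capillary beds, or
any anatomically realistic branching law.  Tests passing on these phantoms
therefore validate the *measurement and simulation machinery* -- that
volumes, surfaces, skeletons, fractal slopes, fluxes and statistics are
computed correctly on known ground truth -- not that real lung satisfies
the same numbers.

# Morphometry choices

* **Unit conversion**: physical sizes are converted to voxels by rounding
  (830 um at 13.2 um -> 63 voxels); the conversion is recorded in the ROI
  table.
* **"Median pixel average"**: read as the median of the pleural distances
  over the ROI's tissue voxels; the median is named first in the source
  description and is robust.  Classification is strict:
  `median < 830 um` is subpleural.
* **Surface area** uses a marching-tetrahedra triangulation of the 0.5
  isosurface after a 3-cube box-mean smoothing of the binary mask;
  voxel-face counting overestimates curved surfaces by ~50% and raw
  midpoint triangulation by ~28%, while the smoothed triangulation is
  within ~2% on a radius-10 digital sphere (and 5% is the accepted
  tolerance).
* **Fractal dimension**: corner-aligned box counting at sizes 2, 4, 8, ...
  up to a quarter of the smallest grid dimension; `D` is minus the
  least-squares slope of `log N` against `log s`.  Whether the original
  tool optimised box-grid translation is unknown; corner alignment is the
  simplest reproducible choice.  Masks are excluded (not errored) when
  empty, when fewer than three scales are usable, when counts do not vary,
  or when the mask's bounding box is under 4 voxels across -- mirroring
  the exclusion of VOIs containing only small partial vessel volumes.
* **Skeletonisation**: topology-preserving 3D thinning (26-connected
  foreground / 6-connected background simple-point test, six directional
  sub-iterations, sequential re-checking, endpoints preserved) with fixed
  raster order for determinism.  Junction voxels (more than two
  neighbours) merge into junction nodes when adjacent; branches are
  maximal paths between end/junction nodes; branch path length is
  measured on a 5-point moving-average smoothing of the voxel polyline
  with pinned endpoints, because raw chain-code length overestimates
  smooth curves by ~5-7% (the quarter-arc oracle then lands within 0.2%
  of `(pi/2)/sqrt(2)`), while straight lines and the tortuosity >= 1
  bound are untouched.  Tortuosity per VOI is the unweighted mean over
  branches (the aggregation is not stated in the source; unweighted is
  the simplest), and zero-chord loops are excluded and counted.
* The VOI refinement study ("no variance above this size") is an optional
  report, not a gate: `measure_voi` on growing boxes is trivial to script
  and the package does not hard-code a verdict.

# Model preparation

Per-class binary masks are upsampled by nearest-neighbour replication
(factor 3 by default -- replication by 3 along each axis, 27 children per
voxel; the source text's "9" reads as an editorial slip, as does its "9
cubic voxels" for the median window, implemented as 3x3x3), median
filtered, and combined with lymph-over-blood-over-tissue precedence (the
two boolean subtractions).  Lumen components not 26-connected to any
domain face are removed and counted.  The `shrinkage_scale` factor (x2 in
the fixation-shrinkage scenario) multiplies the voxel pitch, changing
every physical length while leaving the voxel grid untouched.

The three "distal" faces are the face opposite the pleural face plus the
two lateral faces whose lumen openings lie at greater mean pleural
distance (a fixed face order breaks ties); the source does not state which
three of the five non-pleural faces were used, so the rule is explicit and
overridable via `distal_faces`.

For the shipped flow analyses the synthetic VOIs are prepared with
`upsample = 1, median_window = 1`: the phantoms are noise-free by
construction, and upsampling would triple the grid in each direction
without changing the geometry.  The x3 + median-3 path remains the
default of the study-style pipeline and is covered by exact
fraction-preservation and pruning tests.

# Statistics

`mann_whitney_u()` computes the exact two-sided p (dynamic-programming
null distribution of U) whenever both groups have at most 12 observations
and there are no ties, and a tie- and continuity-corrected normal
approximation otherwise; the method used is recorded.  Tests cross-check
both branches against full enumeration and against `wilcox.test`.
Distance regressions report the signed Pearson r (the source prints
positive r while describing inverse correlations, so `abs_r` is also
carried), the t-test p -- identical to the slope test in simple
regression -- and the least-squares line, with excluded records counted.
No multiple-testing correction is applied by default; a Bonferroni column
is optional.

# Known limitations

* **Membrane-dominated sensitivity.** In the x100 protocol the lymphatic
  inlet velocity reproduces the reported response structure (a large
  uptake *decrease* at x100 as the lumen pressurises toward the
  interstitial pressure, a small *increase* at /100).  Because the model
  is linear, the two perturbations sit in an exact -100:1 ratio of uptake
  changes -- a ratio the reported -82.7%/+0.8% pair also satisfies to
  within a few percent, which is a useful consistency check on both
  implementations.  The membrane
  conductivities, however, change the uptake far above the grid-refinement
  error in these phantoms, whereas the study found them inconsequential.
  The reason is geometric: `1/K` equals roughly 2 mm of interstitium per
  unit area, so wall perturbations disappear only when the interstitial
  path resistance dominates -- which requires the ratio of vessel-wall
  area to septal flow cross-section to exceed ~250, as in real parenchyma
  with sub-resolution septa and large sheet-like lymphatic surfaces.  At
  13.2 um pitch with >= 1-voxel septa and ~0.33-0.45 air fraction the
  phantom cannot reach that regime, so this finding is reported as
  geometry-limited rather than tuned for.
* Cyclic strain, Starling osmotic terms, non-Newtonian rheology and
  capillary networks are out of scope, as in the steady source model.
* The thinning algorithm produces curve skeletons; sheet-like collapsed
  lymphatics reduce to centrelines, which is also what the reference
  skeleton tool does, but means "branches" through a sheet depend on its
  outline.
* The Reynolds-number regime is an assumption (creeping flow), not a
  computed quantity: no length scale is prescribed for it, so the package
  does not report one.
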