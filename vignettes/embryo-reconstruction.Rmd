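---
title: "Reconstructing cell lineages from 3D+time microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cell lineages from 3D+time microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`embryotrack` reconstructs cell lineage trees from 3D+time fluorescence
recordings of developing embryos with fluorescently labelled nuclei (and
optionally membranes). The pipeline follows the established PDE-based
workflow for this problem: nonlinear geometric filtering, nucleus centre
detection, optional shape segmentation, and combinatorial tracking with
mitosis detection, scored against curated gold standards. This vignette
explains each model, the numerical schemes behind it, the tunable
parameters with their units and defaults, and the design choices that were
genuinely open.

## Image model and conventions

A recording is a `timelapse_dataset`: per frame, one `voxel_grid` per
channel. Arrays are indexed `[z, y, x]`; voxel spacing `(sz, sy, sx)` is in
micrometres and may be anisotropic — every derivative, Gaussian kernel and
distance in the package works in physical micrometres, so anisotropic
stacks are handled throughout. Physical positions use the centre-of-voxel
convention `physical = (index + 0.5) * spacing`, with positions reported as
`(x, y, z)`. Intensities are never rescaled on load: thresholds are either
absolute or stated as fractions of a per-frame maximum, and each function
documents which.

Lineages are `lineage_forest` objects: a union of disjoint trees whose
nodes are nucleus centres and whose edges connect a centre at time `t` to a
centre at `t + 1`. The structural invariants — at most one mother, at most
two daughters, links spanning exactly one frame — are enforced by
`validate_forest()` and hold for every tracker output. The on-disk format
is a plain CSV (`id, t, x, y, z, mother_id, virtual`, with `mother_id = -1`
for roots and positions stored to 6 decimal digits); gold standards use the
same format plus an optional `curated` flag and optional space–time scope
boxes.

## Filtering: geodesic mean curvature flow (GMCF)

Denoising uses the level-set geodesic mean curvature flow

$$u_t = |\nabla u|_\varepsilon \,
  \nabla \cdot \Big( g\big(|\nabla G_\sigma * u|\big)
  \frac{\nabla u}{|\nabla u|_\varepsilon} \Big),
  \qquad g(s) = \frac{1}{1 + K s^2},$$

which moves each intensity level set by its mean curvature, modulated by
the edge indicator `g` evaluated on the Gaussian-pre-smoothed gradient.
Homogeneous regions (noise) are smoothed aggressively while strong edges,
where `g` is small, are preserved and even sharpened. With `K = 0` the flow
reduces to pure mean curvature motion.

Parameters (`gmcf_params`): `K` (1/(intensity/µm)²; default 0.01, suited to
O(100)-count contrasts), `sigma_pre` (µm; default 1), `n_iter` (default 5,
the filtering depth used throughout the benchmark runs), `tau` (scheme
units; a stability-bounded default `0.2 / Σ 1/h_k²` is derived from the
spacing).

**Numerics.** The package uses an explicit finite-difference scheme in flux
form: face-centred gradients, face-averaged conductances, Evans–Spruck
regularization `|∇u|_ε = √(|∇u|² + ε²)` with `ε = 10⁻⁴ ×` the intensity
range, and zero-flux (reflective) boundaries, which fall out of
edge-replicated shifts and avoid edge darkening. Each update is passed
through a monotone limiter that clamps the new value into the local
6-neighbourhood range of the previous iterate. The limiter makes the
discrete maximum principle *exact*: a constant image is a fixed point and
global extrema can never amplify, which the test suite asserts to 1e−9.
Production-scale implementations of these flows typically use semi-implicit
co-volume schemes on cluster hardware; this package deliberately uses the
standard explicit scheme — same continuous PDE, simpler and dependency-free
— and gates fidelity on qualitative invariants instead (extremum
non-amplification, variance reduction on noise, blob-position stability,
shrinkage of level-set volumes under pure curvature flow).

## Centre detection

Two alternative detectors produce a `centre_set` per frame; either output
feeds segmentation and tracking.

**FBLS (flux-based level-set) detection**, for dense populations. The
filtered image evolves so that its isosurfaces move with normal velocity
`V = δ + μk` (`k` the mean curvature): every level set shrinks and
smooths, the intensity landscape is progressively simplified, and the
number of local maxima decreases monotonically until nuclei survive as
isolated humps. The advection part is discretized with the Osher–Sethian
upwind gradient, the curvature part shares the GMCF machinery, and the same
monotone limiter applies. `extract_local_maxima()` then takes voxels that
dominate their 26-neighbourhood, discards those below
`intensity_floor × frame maximum` (default 0.2), and merges equal-valued
plateaus to their centroid; 26-connectivity and plateau merging keep the
rule rotationally unbiased. Defaults: `delta = 0.5` µm/time, `mu = 1`,
`n_iter = 10` (the pipeline uses `delta = 0.2`, gentle erosion that
preserves half-intensity telophase nuclei).

**DoG (difference of Gaussians) detection**, for sparse, high-contrast
populations. The band-pass response `G_small * u − G_large * u` (sigmas in
µm, defaults 2 and 14, converted per-axis to voxels) is thresholded at
`threshold_pct`% of its per-frame maximum (default 5%); each 26-connected
component above threshold yields one centre at its response-weighted
centroid. Referencing the threshold to the per-frame response maximum makes
detection exactly equivariant to intensity rescaling. Because connected
components merge when blob responses overlap, DoG resolves nuclei only when
their spacing is several response widths — FBLS is the right choice at
gastrulation densities, and the package's pipeline default is FBLS. Rather
than interactive visual parameter picking, `embryotrack` provides
`dog_parameter_scan()`, which scores parameter combinations against
curated centres when a gold standard exists.

## Shape segmentation: subjective surfaces (SubSurf)

Seeded segmentation evolves a segmentation function under

$$u_t = w_d\, |\nabla u|_\varepsilon\,
  \nabla\cdot\Big(g \frac{\nabla u}{|\nabla u|_\varepsilon}\Big)
  + w_c\, \nabla g \cdot \nabla u,$$

an edge-gated diffusion (weight `w_d`) plus an advection that transports
level sets towards edge minima of `g` (weight `w_c`). With the
regularization `eps` of order 1 the flow operates in its
diffusion-dominated "graph" regime: the function floods the region bounded
by edges, pours across gaps only slowly, and the advection term piles level
sets up at the boundary — which is what lets the method complete contours
across heterogeneous or missing membrane staining. The conductance is
`g = 1/(1 + K|∇G_σ*I|²)` for nucleus and whole-embryo targets, and
`g = 1/(1 + K (G_σ*I)²)` for membrane targets, where the bright membrane
signal itself marks the boundary. The package implements the edge-stopped
advection–diffusion family with `w_c`, `w_d` as the weights of the two
terms.

The initial function is a radially decreasing peak at the seed,
`u0 = 1/(1 + (|x − seed|/h)²)` with `h = 5` µm. Any peaked profile is
admissible; the squared decay was chosen because its exterior tail is low
enough that the relative threshold (mask = `{u ≥ iso_fraction · max u}`,
`iso_fraction = 0.5`) cleanly separates object from background. The mask is
post-processed to the connected component containing the seed, with
interior holes filled; a mask touching the image border raises a warning
flag. On a 6 µm sphere phantom the defaults recover the analytic volume
within 15% and the boundary within 2 voxels Hausdorff distance, and
re-seeding at the mask centroid reproduces the mask with Jaccard ≥ 0.9.

`segment_embryo()` applies the same equation to the whole tissue: the
nucleus channel is smoothed with `g_sigma = 8` µm (of the order of the
internuclear distance) so individual nuclei merge into one bright mass,
seeded at the intensity centroid. Because the object spans the field of
view, the evolution runs on a 3×-block-averaged coarse grid, where a few
hundred diffusion steps traverse the tissue; the mask is then upsampled to
the input geometry. `cell_density()` divides the centre count inside the
mask by its physical volume. Per-cell segmentation is intended to run on
validated or accepted centres — the CLI takes a centre list and never
auto-detects internally.

## Tracking: three stages around a cost function

Tracking turns per-frame centre sets into a lineage forest in three
stages.

**Stage 1 — nearest-neighbour initialization.** Each centre at `t + 1`
links to its nearest centre at `t` within `d_max`. Daughters choose
mothers, so a division (two daughters electing one mother) is representable
without special cases; the direction is a package choice. The result may
violate the two-daughter limit; violations are recorded, not rejected.

**Stage 2 — simulated annealing.** The forest cost is a weighted sum of
per-term contributions, each expressing one prior biological requirement;
the quadratic forms below are the package's definitions of those
requirements, all normalized by `d_max` to be unit-free:

| term | form | default weight |
|---|---|---|
| multi-mother (hard) | count of extra mothers | 10⁴ |
| excess daughters (hard) | count of daughters beyond 2 | 10⁴ |
| motherless | centres at `t > 0` with no mother | 10 |
| disappearance | centres before the last frame with no daughter | 10 |
| displacement | Σ (link length / d_max)² | 1 |
| division interval | division pairs < `tau_div` frames apart on one branch | 5 |
| inertia | Σ ‖v_t − v_{t−1}‖² / d_max² over consecutive links | 0.5 |
| sister symmetry | Σ ‖v_A − v_B‖² / d_max² over daughter pairs | 0.5 |

The disappearance term encodes the no-cell-death assumption valid at these
developmental stages; `allow_disappearance = TRUE` zeroes it for systems
where death occurs. `tau_div` (default 10 frames) is the shortest credible
interval between successive divisions of one branch. The weights were
fixed after initial trials on synthetic recoveries and are recorded in the
configuration — they are calibration constants of the method, gated by the
oracle and recovery tests, not per-run tuning knobs.

The annealer proposes random moves — rewire a centre's mother among its
`k_candidates` nearest predecessors, delete a link, create a link for a
motherless centre, or swap the mothers of two contemporaneous centres —
and accepts with probability `min(1, exp(−Δ/T))` (always, for
cost-decreasing moves), with `T` falling linearly from `T0` to 0 over
`n_sweeps` sweeps; `T = 0` is strict descent. Move evaluation is
incremental: each proposal recomputes only the cost terms its link change
can touch (including division-interval terms within a `tau_div` window of
the affected subtrees), which the tests verify against the full
recomputation by requiring exact agreement between the annealer's final
cost and `forest_cost()`. After the schedule, any residual excess-daughter
violation is resolved exactly by detaching the worst daughters — with the
hard weight four orders of magnitude above the soft terms this is always
cost-decreasing — so the output satisfies the hard constraints exactly. On
exhaustively enumerable two-frame instances, best-of-20-restart annealing
attains the global minimum on all tested instances.

**Stage 3 — repair.** Candidate edits are (i) deleting isolated trees
spanning fewer than `L_min` frames (default 3) — detections that "lived"
only briefly — and (ii) bridging one-frame gaps: a track ending at `t` and
a track starting at `t + 2` within `2·d_max` are joined through a *virtual
centre* at the spatial midpoint, flagged `virtual = TRUE` and excluded from
detection scoring. The edit subset is selected by the same annealing
machinery over edit toggles, scored by the full forest cost; a coherent
forest is returned unchanged.

All three stages are deterministic given the config seed.
`propagate_labels()` pushes labels (e.g. a fate map at some stage) down the
forest through divisions; conflicts are impossible because every centre has
a single mother.

## Validation metrics

Scoring a reconstruction against a gold standard proceeds per frame.
Detected and curated centres are matched one-to-one within a radius of
`r_factor ×` the mean internuclear distance — defined as the mean
nearest-neighbour distance among gold centres of that frame.
`r_factor` defaults to 0.5, the midpoint of the accepted 0.2–0.6 working
range. The matching maximizes the number of matches, then minimizes total
distance (solved as a maximum-weight bipartite matching); the one-to-one
rule prevents one detected centre from serving two gold centres, on
unambiguous fixtures this is verified equivalent to a plain neighbourhood
query, and against brute-force enumeration in general.
TP + FN always equals the gold count.

Link errors are counted from `t` to `t − 1` within the TP subset: a
correct detected mother is a TP link; a detected mother that maps elsewhere
is a *wrong link* (WL, counting as both FP and FN); no detected mother is a
*missing link* (ML, FN only); `FN = WL + ML` by construction. A gold
division whose mother and both daughters are TP counts as a mitosis TP only
if both daughter links are present — detecting two separate nuclei is not
enough; they must be linked back to their mother, otherwise the tree lacks
its junction. Rates are `sensitivity = TP/(TP+FN)`,
`false detection rate = FP/(TP+FP)`, `FN rate = FN/(TP+FN)`; empty
denominators yield `NA`, never 0. The *global lineage score* is the product
of centre-detection and linkage sensitivity — linkage alone can look good
while missing many centres, so it is weighted by the detected proportion.
Scope boxes restrict all counting to curated regions and windows on both
the gold and the detected side.

## The synthetic embryo generator

Every stage is testable without external data through
`synthetic_config()` / `simulate_ground_truth()` / `render_embryo()`. The
generator emulates the imaging regime of early-embryo nuclear recordings;
its defaults are the package's benchmark conditions and were fixed once:

* **Population and field.** 100 initial cells in a 110 × 110 × 55 µm field
  at 1.37 µm isotropic voxels (a typical confocal zebrafish configuration),
  8 µm nuclear exclusion distance — giving a mean internuclear distance
  near 10 µm — for 30 frames at 67 s.
* **Motion.** Coherent drift (0.4, 0.2, 0.1) µm/frame plus an isotropic
  random walk of 0.5 µm/frame (an optional swirl field adds rotational
  flow), so per-frame displacement stays well below half the internuclear
  distance, as in the emulated recordings.
* **Divisions.** Each eligible cell divides with probability 0.01 per
  frame (a ~2 h cell cycle at 67 s frames); daughters are placed ± one
  nucleus sigma around the mother along a random axis and rendered at half
  intensity in their first frame, mimicking telophase. A refractory period
  of 30 frames (33.5 min, a conservative lower bound on the cell-cycle
  length at these stages) prevents biologically impossible re-divisions
  minutes after birth. There is no cell death.
* **Exclusion.** Soft repulsion acts on all nuclei each frame, including
  newborn sisters: two passes, each removing a quarter of the remaining
  overlap per cell, so sisters separate over a few frames the way real
  telophase nuclei do.
* **Rendering.** Nuclei are anisotropy-aware Gaussian blobs (σ = 2 µm,
  peak 100 counts over a background of 10), with peaks attenuated by
  `exp(−0.003 z)` to emulate signal degradation with imaging depth,
  Gaussian read noise (σ = 4 counts), and quantization to integer camera
  counts — which also makes TIFF round-trips exact. An optional membrane
  channel renders shells at 1.8 σ. A `"ball"` domain variant confines
  cells to the inscribed ellipsoid for whole-embryo segmentation tests.

What the generator does *not* emulate: textured chromatin and mitotic
figures beyond the two-blob approximation, PSF anisotropy beyond per-axis
sigmas, scattering, bleaching, or optical aberrations. Passing the recovery
gates therefore demonstrates that the algorithms meet their contracts under
controlled, idealized imaging — not that any particular real recording
will reach the same rates.

Under these conditions the full pipeline (GMCF 5 iterations → FBLS →
annealed tracking) recovers ≥ 99% of centres, ≥ 95% of links and ≥ 80% of
mitoses against the generator's truth; `scripts/acceptance.R` recomputes
these rates from scratch at any seed.

## Problem sizes and runtime choices

The default benchmark (100 cells growing to ~130, 30 frames of
80 × 80 × 40 voxels) runs the full pipeline in about two minutes on one
CPU; the test suite uses this size for the end-to-end recovery check and
much smaller phantoms (18–30 voxels per axis, 2-frame tracking instances
with ≤ 5 centres per frame against exhaustive enumeration, 50 seeds)
everywhere else. These sizes are the package's chosen trade-off between
statistical resolution and convenient test turnaround. The annealer runs
40 sweeps in the pipeline default; the oracle tests use 200 sweeps on tiny
instances where the exhaustive optimum is known.

## Known limitations

* The explicit PDE schemes trade speed for simplicity; production-scale
  volumes (10⁹ voxels per frame) would need semi-implicit or co-volume
  solvers, or a compiled backend.
* Segmentation quality is asserted on phantoms; quantitative validation of
  shape segmentation against manual outlines remains out of scope.
* The cost-term formulas are the package's own quadratic encodings of the
  biological requirements; different forms would give a different (but
  similarly gated) tracker.
* DoG detection is honest about its regime: it merges nuclei closer than a
  few response widths and is intended for sparse, high-contrast material.
* Configuration files use YAML sections mirroring the parameter objects
  (an available, well-supported format for key/value sections with the
  same structure as the documented configs).
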