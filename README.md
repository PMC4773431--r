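# embryotrack

Reconstruction of cell lineage trees from 3D+time fluorescence microscopy
of developing embryos.

Modern light-sheet and confocal imaging can follow every nucleus of an
early embryo for hours, but turning those multi-gigabyte recordings into a
*digital embryo* — a lineage forest giving each cell's position, track and
divisions — requires a chain of image-analysis steps whose errors
compound. `embryotrack` implements that chain as a tested R library plus a
command-line interface, exercised end-to-end on synthetic embryos with
known ground truth:

1. **Filtering** — geodesic mean curvature flow (GMCF): level sets of the
   intensity move by mean curvature, gated by the edge indicator
   `g(s) = 1/(1 + K s²)`, smoothing noise while preserving nuclear edges.
2. **Nucleus centre detection** — either flux-based level-set (FBLS)
   simplification, which moves isosurfaces with normal velocity
   `V = δ + μk` until nuclei survive as isolated local maxima (dense
   tissue), or difference-of-Gaussians (DoG) blob detection (sparse,
   high-contrast material).
3. **Shape segmentation** (optional) — subjective-surface (SubSurf)
   evolution of a seeded segmentation function under edge-stopped
   diffusion–advection, for nucleus/cell shapes and for the whole embryo
   volume with cell-density estimation.
4. **Tracking** — a three-stage tracker: nearest-neighbour link
   initialization; simulated annealing (acceptance `min(1, exp(−Δ/T))`,
   linear temperature schedule) against a cost expressing single-mother /
   two-daughter constraints, no cell death, bounded displacement, division
   spacing, inertia and sister symmetry; and repair, which deletes short
   spurious branches and bridges one-frame gaps with virtual centres.
5. **Validation** — gold-standard scoring: one-to-one centre matching
   within a fraction of the mean internuclear distance, link errors split
   into wrong links (WL, counted as FP *and* FN) and missing links (ML),
   mitosis detection within the true-positive subset, and the rates
   sensitivity = TP/(TP+FN), false-detection rate = FP/(TP+FP), FN rate =
   FN/(TP+FN), plus the **global lineage score** = centre sensitivity ×
   linkage sensitivity.

A synthetic-embryo generator (`synthetic_config()`, `synthetic_embryo()`)
renders ground-truth lineages as image stacks — Gaussian-blob nuclei with
depth-dependent signal loss, camera noise, coherent motion, divisions with
telophase rendering, no cell death — so every stage is testable with no
external data.

## Worked example

Generate a small embryo, reconstruct it, and score the reconstruction
against the generator's truth:

```r
library(embryotrack)

cfg <- pipeline_config(
  input = list(type = "synthetic",
               config = synthetic_config(n_cells_initial = 30, n_frames = 10,
                                         box_size = c(70, 70, 40), seed = 5)),
  seed = 5)
res <- run_pipeline(cfg, "run1")
res$report
#> <score_report>
#>   centres  TP=313 FP=2 FN=0  sensitivity=1 fdr=0.006349
#>   links    TP=283 FP=0 FN=0  sensitivity=1 fdr=0
#>   mitoses  TP=2 FP=0 FN=0  sensitivity=1 fdr=0
#>   lineage score = 1
```

Reading the output: all 313 true nucleus positions over 10 frames were
detected within half the mean internuclear distance (centre sensitivity
100%, with 2 spurious detections giving a 0.6% false-detection rate); all
283 scoreable mother links were reconstructed, with no wrong links; both
divisions in this clip were found with each daughter linked back to its
mother. The lineage score multiplies the first two sensitivities. `run1/` now holds the detected centres and the lineage as
CSV, the score report as JSON, and a manifest recording every parameter
and seed — re-running from the same manifest reproduces each file
byte-identically.

The same stages are available individually (`gmcf_filter()`,
`detect_centres()`, `subsurf_evolve()`, `segment_embryo()`,
`track_centres()`, `score_lineages()`), and from the shell:

```sh
Rscript inst/cli/embryotrack.R synth --seed 5 --out data/
Rscript inst/cli/embryotrack.R detect --in data/synth_nuclei_t000.tif --method fbls
Rscript inst/cli/embryotrack.R run --config pipeline.yaml --out run1/
```

## Documentation

The methods vignette (`vignettes/embryo-reconstruction.Rmd`) describes the
PDE models and their explicit finite-difference schemes, the tracking cost
terms and annealing schedule, the validation protocol, the synthetic
generator's assumptions, and the package's design decisions and known
limitations.
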