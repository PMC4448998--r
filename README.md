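# embryo4d

Quantification of spatio-temporal reporter expression from 4D (3D + time)
fluorescence recordings of developing embryos, recorded with auto-exposure
feedback on ordinary widefield microscopes.

Long fluorescent recordings of light-sensitive embryos face a dynamic-range
problem: reporter signal often grows by orders of magnitude, so any single
camera exposure either saturates late development or loses early expression
in quantization noise. The workflow implemented here adjusts the exposure
time *during* acquisition by feedback — if the k-th largest count of the
last stack leaves a threshold band, the exposure is divided/multiplied by a
correction factor within hard bounds (15–200 ms by default) — and records
every exposure in the metadata. Post processing then reconstructs a
calibrated intensity series

> v'(x, t) = max(0, raw(x, t) − b(t)) / exposure(t),   then s(t) · v'

with the background b(t) estimated per frame as the minimum over
inside/outside the embryo shell of the 40–60-percentile *filtered average*,
and with chained continuity factors s(t) that make the in-shell mean exactly
continuous across every exposure change. The result extends the usable
brightness range by roughly `exposure_max/exposure_min` (~an order of
magnitude) beyond the fixed-exposure camera.

Downstream, recordings are aligned onto a normalized developmental time axis
(anchors: first blastomeres = 0, gastrulation = 10, ventral enclosure = 43,
2-fold tail = 54, piecewise linear, capped at 100) and reduced to
expression summaries:

* **T** — total in-shell signal over time;
* **APT / DVT / LRT** — 20 slices along the anterior-posterior axis (major
  shell axis) or the founder-frame dorsal-ventral / left-right axes, over
  time;
* **XYZ** — a cube grid aligned with the founder frame (origin at the
  centroid of ABa, ABp, EMS, P2), over time;
* **SC** — approximate single-cell expression: a reference 4D cell model is
  superimposed via a similarity transform fitted to the four founders, and
  every in-shell voxel is Voronoi-assigned to the nearest model nucleus.

Profiles are compared by Pearson correlation (also Manders overlap or
Euclidean distance), exported as square PHYLIP distance matrices for
external tree programs, and clustering trees are scored with the statistics
μ (leaf-pair edge distance), r = max μ, d = mean minimum same-gene μ,
D = its expectation under random leaf-label permutation, and the quality
ratio **q = (d − 2)/(D/2)** (0 when every repeated reporter clusters as
siblings). T profiles can additionally be correlated against staged
bulk-expression tables with a bootstrap significance.

A synthetic-recording generator (toy dividing lineage, Gaussian point
spread, linear camera with shot/read noise and saturation, drifting
background, anchor events, and the real feedback controller in the loop)
provides ground truth for every stage, so the whole pipeline is testable
without a microscope.

## Worked example

```r
library(embryo4d)

model <- generate_reference_model(n_rounds = 2, seed = 1)
model
#> reference cell model: 28 cells (16 leaves), 2 division rounds

sim <- generate_recording(
  model,
  geometry = recording_geometry(c(48, 32, 12), c(1, 1, 2)),
  channel  = channel_config(stack_interval = 120, z_slices = 12),
  anchors  = anchor_annotations(0, 180, 774, 972),
  duration_s = 1800, seed = 7)
rec <- sim$recording
head(rec$channels$fluor$meta, 8)
#>   time_s exposure_ms stat
#> 1      0         100  100
#> 2    120         200  103
#> 3    240         200  107
#> 4    360         200  110
#> 5    480         200  113
#> 6    600         200  117
#> 7    720         200 4095
#> 8    840         100 4095
```

The controller lengthens the exposure while the scene is dim (statistic
below the lower threshold), then halves it as expression turns on and the
rank-10 statistic saturates. Reconstruction and normalization undo the
exposure changes and put the recording on the 0–100 axis:

```r
series <- normalize_recording(reconstruct_series(rec), rec$anchors)
series
#> calibrated series 'syn0007': 16 stacks, exposures 15-200 ms, time-normalized

mask <- make_shell_mask(series$shell, series$geometry)
apt <- extract_APT(series, mask, founders = rec$founders)
apt
#> APT expression profile of 'syn0007' (synthetic): values 101 x 20 on 101 time points
round(apt$values[seq(1, 101, 25), 4:9], 1)   # a few AP slices over time
#>      [,1] [,2] [,3]  [,4]  [,5]  [,6]
#> [1,]    0    0  0.0   0.0   0.0   0.0
#> [2,]    0    0  0.0   0.0   0.0   0.0
#> [3,]    0    0  0.0   0.0   0.0 108.1
#> [4,]    0    0 58.0 471.6 965.7  83.2
#> [5,]    0    0  5.4  82.5 418.6  89.3
```

Rows are normalized times 0, 25, 50, 75, 100; columns are anterior→posterior
slices; values are calibrated signal (counts/ms) per slice — expression
switching on mid-development, localized around slices 7–9.

Tree quality of a clustering, on a hand-drawn 6-leaf example with three
duplicated reporters:

```r
tree_quality("((A1,A2),((B1,C1),(B2,C2)));",
             c(A1 = "A", A2 = "A", B1 = "B", C1 = "C", B2 = "B", C2 = "C"),
             n_boot = 1000, seed = 1)
#> tree quality over 6 leaves (3 duplicated genes):
#>   r (max leaf distance)        = 5
#>   d (mean min same-gene dist)  = 3.333
#>   D (random-label expectation) = 4.136  [1000 permutations, seed 1]
#>   q = (d - 2)/(D/2)            = 0.6447
```

Gene A's two recordings are siblings (distance 2); B's and C's are 4 edges
apart, so d = (2 + 4 + 4)/3 ≈ 3.33, and q > 0 reflects the imperfect
grouping.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "embryo4d.R", package = "embryo4d"))')" \
  simulate --out rec/ --seed 1
```

Subcommands: `simulate`, `reconstruct`, `normalize`, `profile`
(`--kind T|APT|XYZ|DVT|LRT|SC`), `compare` (PHYLIP export), `treequal`,
`stagecorr`. Flags beat `--config` JSON values, which beat built-in
defaults; every run is deterministic given `--seed`.

## Layout

* `R/` — implementation: generator (`generate_reference_model`,
  `generate_recording`), controller (`kth_largest`, `propose_exposure`,
  `run_acquisition_loop`), reconstruction (`filtered_average`,
  `estimate_background`, `reconstruct_series`), time normalization
  (`map_time`, `normalize_recording`, `map_time_per_cell`), profiles
  (`extract_T/APT/XYZ`, `extract_axis_profile`, `build_xyz_frame`),
  single-cell mapping (`fit_similarity_transform`, `assign_voxels`,
  `extract_SC`), comparison (`similarity`, `distance_matrix`,
  `tree_quality`, `stage_correlation`), I/O (`write_recording`,
  `write_phylip`, ...) and the CLI (`e4d_cli`).
* `vignettes/quantification-methods.Rmd` — the model, parameter meanings,
  numerical conventions and design rationale.
* `tests/testthat/` — unit, property and end-to-end suites on synthetic
  recordings.
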