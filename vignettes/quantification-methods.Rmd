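---
title: "Quantifying 4D reporter expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 4D reporter expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryo4d)
```

## The problem

Continuous fluorescence recording of a developing embryo with a conventional
widefield microscope faces three coupled problems. First, the sample is
killed by light, so exposure must be minimal; but reporter signal typically
grows by orders of magnitude over development, so a single exposure time
either saturates late frames or buries early ones in quantization noise.
Second, embryos develop at slightly different tempos, so recordings cannot
be compared frame-by-frame. Third, the quantity of biological interest is
expression *per region or per cell*, not per camera pixel.

`embryo4d` implements one coherent answer: exposure time is adjusted by
feedback *during* acquisition and stored per stack; post processing undoes
the exposure variation to recover a calibrated intensity series; annotated
morphological events map each recording onto a common developmental time
axis; and the calibrated, time-normalized volumes are reduced to a family of
expression summaries (T, APT, DVT, LRT, XYZ, SC) that can be compared and
clustered across recordings. A synthetic-recording generator with full
ground truth makes every stage testable without a microscope.

## Auto-exposure feedback

The controller examines the last acquired stack and computes its *k*-th
largest count (default `k_index = 10`). Using a rank statistic instead of
the maximum means a handful of hot pixels or shot-noise outliers cannot
trigger an exposure change. While this statistic stays inside a user band
(defaults: 25% and 75% of the camera full scale) the exposure is untouched —
deliberately, because intensity is not perfectly linear in exposure time and
needless changes would inject steps into the record. When the statistic
leaves the band, the exposure is divided or multiplied by
`correction_factor` (default 2) and clamped to
`[exposure_min, exposure_max]` (defaults 15–200 ms, the band we consider
safe for long recordings of light-sensitive embryos).

Relevant parameters of `channel_config()`:

| parameter | default | meaning |
|---|---|---|
| `k_index` | 10 | rank of the robust maximum (counts) |
| `lower_threshold`, `upper_threshold` | 25% / 75% of full scale | feedback band (counts) |
| `correction_factor` | 2 | multiplicative exposure step |
| `exposure_min`, `exposure_max` | 15, 200 ms | hard exposure bounds |
| `stack_interval` | 120 s | one fluorescent stack per three 40-s DIC stacks |

The decision for stack *t + 1* uses only stack *t* (pure feedback, no
look-ahead), and exposures change only at stack boundaries. Saturated voxels
deliberately participate in the statistic: saturation pushes it over the
upper threshold, which is exactly the trigger one wants.

The statistic is computed over the full 3D stack rather than a single slice;
the stack is the acquisition unit, and a per-slice rule would make the
decision depend on arbitrary slice ordering.

## Dynamic-range reconstruction

Counts are turned into calibrated intensities (counts/ms) in three steps.

**Background.** Per frame, the background is the *filtered average*: the
mean of the values whose rank fraction lies in the 40–60-percentile band.
It tracks the background distribution continuously over time (unlike the
median on integer counts) and ignores extreme outliers (unlike the mean).
The estimate is computed separately inside and outside the embryo shell and
the *minimum* of the two is used: the outside is normally representative,
but transient bright objects (for example, a hatched larva crawling past)
can contaminate it, and using the inside as a floor also avoids rare
negative-signal frames. Percentile convention: the *i*-th order statistic
of *n* values has rank fraction *i/n*, and the band is half-open
`(band_low, band_high]`; if the band catches no rank (tiny samples) the
median is used. After subtraction, negative voxels are clamped to zero and
the clamped fraction is recorded per stack.

**Exposure normalization.** Each background-subtracted stack is divided by
its stored exposure time.

**Continuity correction.** Because intensity is only approximately linear in
exposure, small jumps can remain exactly at the time points where the
exposure changed. Scanning in time order, whenever the exposure differs from
the previous stack the running scale factor is multiplied by the ratio of
the previous stack's in-shell mean to the current stack's (both after
exposure normalization, both excluding saturated voxels, which are not
linear in exposure); the factor applies to the current and all later stacks.
This makes the in-shell mean exactly continuous across every change by
construction. The continuity statistic is the *in-shell* mean, not the whole
frame: the shell is the annotated object of interest and the outside
contributes mostly background. If the current mean is zero at a change point
(dark early frames), the factor is carried over unchanged and a warning is
logged.

No whole-series model is fitted. A linear least-squares fit across frames
produces smooth-looking series but is systematically biased towards zero
(regression towards the mean), making constant signals decay; a regression
test asserts that calibrated totals of a constant emitter do not decay under
any exposure schedule.

The combination of feedback and reconstruction extends the reconstructable
brightness range by about the ratio `exposure_max / exposure_min` (about
13 with the defaults, i.e. an order of magnitude beyond the fixed-exposure
camera): `scripts/acceptance.R` measures this fold gain on a simulated
brightening emitter.

## Normalized developmental time

Four annotated events anchor each recording to the common axis: appearance
of ABa (or EMS) at 0, gastrulation at 10, ventral enclosure at 43 and the
2-fold tail stage at 54. `map_time()` interpolates piecewise-linearly
between anchors and is exact at them. After the last anchor the final
segment's slope is reused and the map is capped at 100 — the terminal value
is a cap, not a fifth anchor, because no wall-clock event defines it. Before
the first anchor the first segment's slope extrapolates (possibly to
negative values), and such times are flagged rather than clamped so that no
information is silently destroyed. `normalize_recording()` truncates stacks
mapped past 100. When an annotated lineage is available,
`map_time_per_cell()` instead maps each cell's annotated lifespan linearly
onto the model cell's lifespan; truncation at 100 is applied uniformly
there too.

Profiles are resampled onto a grid of 101 points (0, 1, ..., 100), matching
the granularity of the anchor definition and giving all recordings a common
comparison domain. Grid times outside the recorded span are zero-padded and
marked in an observation mask.

## Expression summaries

All summaries integrate only over the shell mask (voxel centers inside the
annotated ellipsoid; membership by voxel center, with no partial-volume
splitting, so that spatial summaries conserve the total exactly).

* **T** — total in-shell signal per time point.
* **APT** — the AP axis is the major axis of the shell ellipsoid (an error
  is raised if the two longest semi-axes tie, since the axis is then
  ambiguous); the axial extent is divided into 20 equal half-open slices.
  When founder positions are available the end nearer ABa is oriented
  anterior; on a bare ellipsoid the annotated axis orientation is used.
* **XYZ** — voxels are transformed into the founder frame: origin at the
  centroid of ABa, ABp, EMS and P2; AP axis from ABa to P2; DV axis from
  EMS to ABp orthogonalized against AP; LR completing the right-handed
  triple. The frame extent is the larger of |ABa−P2| and |EMS−ABp| enlarged
  by 35% so the cube grid covers the whole embryo (the enlargement exists
  because the founder tetrahedron is strictly inside the shell). Cubes have
  an edge of 20 recording voxels (XY pitch), following the convention that
  cube size is stated in voxels of the recording; a physical-units mode
  would make cube counts comparable across pitches but is not the default.
* **DVT / LRT** — as APT but binned along the frame's DV or LR axis.
* **SC** — see below.

Binning conventions: bins are half-open `[a, b)` with the final bin closed,
and voxels projecting outside the binned span (possible with enlargement
off) are clamped into the nearest end bin, so for every kind the spatial
sums reproduce T exactly (tested at 1e-6 relative tolerance).

## Approximate single-cell mapping (SC)

Without lineaging every recording, approximate per-cell expression is
obtained by superimposing a reference 4D cell model (per-cell positions
over normalized time plus lineage) onto the recording using the four
founder blastomeres. The superposition is a similarity transform — rigid
rotation, uniform scale, translation; 7 parameters — fitted in closed form
(Umeyama/Horn least squares) to the founder correspondences. Four
correspondences determine at most a similarity robustly, and uncompressed
embryos mainly differ by translation, rotation and scale; shear is
deliberately excluded. The transform is fitted once at the 4-cell stage and
held static, relying on uncompressed embryos not rotating during
development; per-time refitting is possible in principle but out of scope.
If the recording starts after the 4-cell stage (up to 8 cells), missing
founder positions are inferred as the average of their two daughters'
positions; later starts are rejected.

At every time point, model nuclei alive at that normalized time are
transformed into recording space and each in-shell voxel is assigned to the
nearest nucleus in physical micrometres (Voronoi polyhedra; the anisotropic
Z pitch is honored through voxel-center coordinates). Every in-shell voxel
is assigned exactly once; exact distance ties go to the lexicographically
smallest cell name for determinism. The per-cell sums, zero outside a
cell's lifetime, are resampled onto the time grid; linear resampling
commutes with summation, so the cell sums reproduce T on the grid too.

The approximation inherits Voronoi's main failure mode: signal from a cell
missing from the model (or from a nucleus closer to a neighbor's territory
than the point-spread width) is credited to neighboring cells. The package
fails loudly when the model has no cells at a time point rather than
silently misassigning.

## Comparing recordings

Profiles are flattened time-major onto the shared grid and compared with
Pearson correlation (the default and, in our experience, the most
discriminating), Manders overlap coefficients (M1, M2; exported scalar =
their mean — a package choice), or Euclidean distance. Pearson similarities
are exported as distances `1 − ρ`. Distance matrices are written in square
PHYLIP format so external tree programs (e.g. Kitsch-style clustering) can
build dendrograms; a minimal UPGMA is included for tests and quick looks
only. The k-coefficient family is not implemented.

Tree quality is judged from reporters recorded multiple times. With leaf
distances μ counted in edges: `r = max μ` over all leaf pairs;
`d = mean over duplicated genes of (min same-gene μ)` — 2 when every
duplicate pair is sibling; `D` = the same statistic under a null in which
the leaf labels are permuted uniformly at random on the *fixed observed
topology* (default 1000 seeded permutations); and the quality ratio
`q = (d − 2)/(D/2)`, small for trees that cluster duplicates tightly.
Fixing the topology isolates label placement quality from tree-shape
effects; on small trees the permutation estimate converges to the exhaustive
enumeration over all label arrangements (tested). `d` is averaged per gene,
not per recording pair, so heavily re-recorded reporters do not dominate.

`stage_correlation()` correlates per-gene T profiles with a staged
bulk-expression table (e.g. microarray series over 4-, 28-, 55-, 95- and
190-cell embryos): each stage is mapped to the normalized time at which the
reference model first reaches that cell count, each shared gene's stage
values are Pearson-correlated with its T profile sampled at those times, and
the significance of the mean correlation is the percentile of the observed
value within a seeded null of random gene pairings. A minimal SOFT-format
reader is provided for loading such tables.

## The synthetic generator

`generate_recording()` emulates the statistical structure the pipeline
assumes, with full ground truth:

* a toy lineage from founders ABa/ABp/EMS/P2, dividing 0–8 rounds; daughter
  nuclei separate by `10/sqrt(g)` µm at round *g* (roughly one cell diameter
  per stage in a ~50 µm embryo) and drift ~1 µm over a lifetime;
* per-cell emission programs (photons/ms over normalized time), rendered
  through an isotropic Gaussian point spread (default σ 1.5 µm), truncated
  at 3σ and renormalized so emitted photons are conserved exactly — which
  makes conservation tests exact;
* a camera with linear gain, optional Poisson shot noise and Gaussian read
  noise, and hard saturation at `2^bit_depth − 1`
  (`counts = clip(round(gain·exposure·photons + background + noise))`);
* slowly drifting background, optional transient bright blobs outside the
  shell (the crawling-object scenario);
* acquisition through the real feedback controller, one fluorescent stack
  per three placeholder DIC stacks 40 s apart;
* anchor events at known wall-clock times, so the true normalized time of
  every frame is known.

Default grid: 150 × 90 × 35 voxels at 0.4 × 0.4 × 1.0 µm (a 0.2 µm native
XY pixel at binning 2; coarse Z sampling keeps light exposure down).
Exact-value tests switch noise off; everything is deterministic given a
seed.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: realistic DIC optics (the DIC channel is a
texture placeholder, never quantified), depth-dependent or anisotropic
point spreads, photobleaching, autofluorescence structure, chromatic
effects, camera nonlinearity (the controller makes no linearity assumption
beyond multiplicative correction, but the simulated sensor is linear), and
real lineage geometry beyond four founders with synthetic descendants.

## Problem sizes and numerical choices

Tests and the acceptance script run on deliberately small scenes — grids
around 16×12×6 to 48×32×12 voxels at 1–3 µm pitch, 15–75 stacks, models of
1–2 division rounds (6 rounds for stage mapping) — chosen so the full suite
completes in well under a minute while every code path (feedback, exposure
changes, saturation, divisions, truncation) is still exercised. The
dynamic-range experiment sweeps a brightness range of ~10^5 so that both
the feedback recording and every fixed-exposure control hit their detection
floor and saturation ceiling strictly inside the sweep.

Numerical conventions collected in one place: 0-based voxel indices on
disk; physical positions are voxel-center micrometres; bins half-open with
closed final bin; rank fraction *i/n* with a half-open percentile band;
Voronoi ties to the lexicographically smallest name; background from
`min(inside, outside)`; continuity factors chained multiplicatively with
carry-over on zero means; similarity fits rejected for coplanar founders
(smallest singular value below 1e-12 of the largest); Pearson undefined on
constant vectors (error rather than NA).

## Known limitations

* The similarity superposition is static; embryos that do rotate during
  recording will smear SC assignments.
* SC accuracy degrades once nucleus spacing approaches the point-spread
  width; the Voronoi partition then splits one cell's signal among
  neighbors (quantified in the test suite: >95% single-cell recovery for
  well-separated cells, ~90% with moderate noise).
* Background estimation is per-frame; slow drifts are tracked but a bright
  object that covers most of the outside *and* raises the inside filtered
  average cannot be fully rejected.
* The 16-bit TIFF container restricts lossless round trips to bit depths
  ≤ 16; calibrated series are stored as scaled 32-bit floats (~1e-7
  relative round-trip error).
* Headline clustering statistics on real recording collections depend on
  those collections; the in-package checks establish correctness of the
  statistics and recovery on synthetic duplicates, not biological
  conclusions.
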