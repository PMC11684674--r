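---
title: "Quantifying medfly embryogenesis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying medfly embryogenesis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryostager)
```

## Scope

`embryostager` quantifies embryonic development of the Mediterranean
fruit fly (*Ceratitis capitata*) from nuclear-labelled light-sheet
time-lapse recordings. It implements four measurement pipelines —
embryo length over developmental time, blastoderm nucleus area and
density in a posterior analysis window, three-dimensional pole-cell
nucleus counting, and germband-tip migration kinematics — together with
a two-level staging model (six embryogenetic events spanning seventeen
stages) and cross-dataset duration statistics. A synthetic-data
generator produces images and staging tables with exact ground truth so
that every stage of the analysis is testable without any recording.

Axis convention: matrix rows run along the rotation axis *y* (the
anterior-posterior axis of an aligned embryo), columns along the
illumination axis *x*, array slices along the detection axis *z*.
Coordinates are 1-based; extents are inclusive pixel counts
(`max - min + 1`).

## The measurement pipelines

### Embryo length

`measureEmbryoLength()` composes crop → 3×3 mean filter → local-mean
threshold (150×150 window) → largest connected component → convex-hull
extent along *y*. The adaptive threshold marks a pixel as foreground iff
it strictly exceeds the mean of the window centred on it; on a large,
nearly uniform embryo this yields a wide connected band along the embryo
outline (where the window mixes embryo and background), whose convex
hull reproduces the embryo silhouette — the hull extent along *y* is the
length. `lengthTimeseries()` normalises by the first frame's length and
by the covered development span; `aggregateCurves()` interpolates series
onto a 1000-point normalised-time grid (linear interpolation; the
alignment granularity is a free choice — 1000 points oversample any
realistic frame rate) and reports the pointwise mean and *n−1* sample
SD. `detectSdPeaks()` reports local maxima of the SD channel by
topographic prominence, the time points where datasets deviate most.

### Blastoderm nuclei

`extractPosteriorWindow()` segments the embryo by Otsu's method, finds
the posterior extreme along *y*, and cuts a 150×150 window whose centre
sits 150 px interior to that extreme on the embryo's centroid column
(the lateral placement is unstated in the field's descriptions; the
midline is the natural choice and both offsets are parameters).
`segmentNuclei2D()` then runs: Gaussian smoothing (σ = 2) → local-mean
threshold (window 15 for the earlier two blastoderm time points with
larger nuclei, 10 for the later one) → hole filling → multi-scale
Laplacian-of-Gaussian seeding (scale ranges (5, 15) and (1, 10)
respectively) → seeded immersion watershed on the inverted smoothed
image → restriction of the watershed to the threshold mask, minus
border-touching objects.

Two design points deserve emphasis:

* **Strict local-mean thresholds mark half of any flat noisy region.**
  Because the comparison is strict and noise is symmetric, a featureless
  background yields a ~50% speckle mask. The nucleus, however, is always
  separated from this speckle sea by a depressed-mean "moat" (the bright
  spot raises the local mean of its surroundings). Each watershed object
  is therefore defined as the connected piece of its masked basin that
  contains the basin's own seed; basins whose seed misses the mask are
  spurious and dropped. Objects smaller than a 3×3 (3×3×3 in 3D)
  neighbourhood are below the resolution floor and discarded.
* **Seed detection.** Seeds are strict spatial maxima of the
  scale-normalised negative-LoG response that are also interior maxima
  across scales (detections at the boundary scales of the range are
  one-sided and typically truncation artefacts: noise-scale or
  cluster-scale blobs). Non-maximum suppression uses the LoG support
  radius √d·σ. A relative response floor (default 0.2 of the maximum
  response) suppresses noise-driven maxima, which at the noise levels
  modelled here stay below ~0.15 of a nucleus response while genuine
  nuclei respond at ≥0.85.

`nucleiStats()` reports counts, per-nucleus projected areas and density
per window (and per µm² when calibrated); `divisionRatios()` forms the
after/before ratios of mean area and density across a synchronous
division wave.

### Pole cells in 3D

`countPoleCells3D()` crops to the region of interest, resamples
anisotropic stacks to isotropic voxels (linear interpolation), rotates
about *y* by the per-dataset alignment angle (bilinear interpolation on
an enlarged canvas), and applies the 3D analogue of the nuclei pipeline:
LoG filtering (the "range 3" is read as σ = 3 by default; the
kernel-size reading σ = 1 is selectable), local-mean threshold (window
15) with hole filling, LoG seeding (scales (1, 10)), and a seeded
watershed on the inverted Gaussian-filtered stack (σ = 2, mirroring the
2D pipeline — a σ = 3 relief merges nuclei separated by ~3σ into one
basin). `summarizeCounts()` reports the cross-dataset sample mean ± SD.

### Germband-tip kinematics

Tip positions are manual annotations (no automatic detection).
`tipKinematics()` accumulates Euclidean steps between successive
annotations scaled to micrometres, and per-interval speeds. The
straight-segment polyline is a lower bound on the dorsal-surface arc
length; with annotation intervals of ~15 min the difference is well
under a percent.

### Staging

`stageCatalog()` fixes the two-level model: events I–VI (blastoderm
formation, early gastrulation, germband elongation, germband
retraction, dorsal closure, muscular movement) spanning stages 1–5,
6–7, 8–11, 12, 13–15 and 16–17. Stages own half-open intervals
`[start, end)` so that `classifyTime()` maps every time to exactly one
stage; the final boundary is closed so the whole span is covered.
`stageDurations(..., normalized = TRUE)` always sums to 1 exactly;
`aggregateStaging()` reports per-stage and per-boundary mean ± sample
SD in absolute hours and normalised development time. Normalisation
uses the observed span of each table; for recordings missing the
earliest stages this is the observed rather than the full span, which
the caller should flag.

## The synthetic-data generator

The generator emulates the statistical structure of the recordings, not
their optics:

* **Embryo movies** (`generateEmbryoMovie()`): an ellipse (semi-axis
  *a* along *y*, default 200 px; *b* = 85 px) scaled over time by a
  relative-length trajectory, uniform body fluorescence over background,
  Gaussian-spot nuclei on the rim, shot (Poisson) plus read (Gaussian,
  σ = 4) noise, quantised to integer grey values as camera data are.
  The default trajectory (`medflyLengthTrajectory()`) is monotone-spline
  shaped: flat through blastoderm and gastrulation, a mild maximum
  during germband elongation, withdrawal to 90% of the initial extent at
  normalised time 0.75 (dorsal closure), partial reversal before
  hatching. True length is `2·a·trajectory(u)` exactly.
* **Nuclei windows** (`generateNucleiWindow()`): *n* isotropic Gaussian
  spots, rejection-sampled at pairwise separation ≥ 4σ and clear of the
  border, on uniform background with the same noise model. Ground-truth
  projected area is operational: the pixels the noise-free pipeline
  response marks (`spotReferenceArea()`). This area follows σ² only up
  to a log-correction from the adaptive threshold (the measured halving
  factor is ~2.4, not 4), which is why `generateDivisionPair()` inverts
  the computed area curve numerically to construct a division event with
  an exact target area ratio, rather than assuming σ/√3.
* **Pole-cell stacks** (`generatePoleCellStack()`): *n* Gaussian blobs
  (σ = 2.5 µm) in a ball of radius 22 µm at separation ≥ 8 µm, the whole
  cluster tilted about *y*, rendered into an anisotropic voxel grid
  (2 × 1 × 1 µm) so that resampling and de-rotation are exercised. The
  generator also reports the region of interest its geometry implies,
  which tests pass as the pipeline's crop.
* **Staging tables** (`generateStageTables()`): per-dataset boundaries
  drawn around a 62-hour mean timetable with per-boundary Gaussian
  jitter, re-sorted to stay monotone. The default timetable follows the
  reported process durations (≈4 h of blastoderm quiescence in stage 5;
  ≈2 h of fast then ≈5.5 h of slow germband-tip migration across stages
  8–10; ≈7.5 h of retraction in stage 12; ≈62 h total).

What the generator does **not** model: optical point-spread, light-sheet
stripe artefacts, bleaching, nucleus shape irregularity and mitotic
figures, intensity gradients across the embryo, or multi-view fusion
geometry. Passing tests therefore demonstrate correctness of the
measurement logic and its noise robustness at realistic SNR, not
performance on raw microscope output.

## Numerical choices

* **Exact thresholding.** Box means and local-mean masks use exact
  integer arithmetic whenever the image is an integer lattice scaled by
  1/d for some d ≤ 1024 (camera data give d = 1, a 3×3-mean-filtered
  image d = 9); the comparison `x·n > Σ` is then exact, so constant
  images produce all-`FALSE` masks and adding an integer offset never
  flips a pixel. For truly continuous images a centred formulation
  (`Σ(x_q − x_p)`) resolves near-ties exactly. A naive box-sum/divide
  provably fails the constant-image contract in floating point.
* **Determinism.** The watershed breaks flooding ties by (relief value,
  queue insertion order), with seeds pushed in list order and
  neighbours enumerated in reading order; component labelling assigns
  labels in reading order of first pixels; `largestComponent()` breaks
  size ties the same way. Re-running any operator is bit-identical, and
  every generator is a pure function of its specification and seed.
* **Windows.** Even-sized threshold windows (150, 10, 2 are all even)
  extend one pixel further towards lower indices; the mean filter
  requires odd kernels.
* **Degenerate inputs.** Constant images are rejected by Otsu
  ("degenerate histogram"); empty masks raise "no object"; empty seed
  sets raise "no markers"; failing movie frames are interpolated with a
  warning and flagged, never silently dropped.

## Problem sizes used in the checks

The test-suite and the acceptance script run entirely on synthetic
data: embryo frames of roughly 360–480 × 160–220 px (semi-axes drawn at
the recordings' scale of a few hundred pixels along *y*), 25-frame
movies, 150×150 nuclei windows with 10–60 nuclei, and 76 µm pole-cell
stacks (~76×76×38 voxels before resampling) with 27 nuclei. These sizes
keep every property at full fidelity — window sizes and filter constants
are the reference values, not scaled-down surrogates.

## Known limitations

* The catalogue of events and stages is fixed; no automatic stage
  recognition from images is attempted.
* Germband-tip positions are manual annotations by design.
* The posterior analysis window is placed from the embryo mask; whether
  the reference measurements used the embryo proper or the vitelline
  outline is not distinguishable from their description.
* The per-dataset numeric stage boundaries of the original recordings
  are not shipped; they are user-supplied CSV inputs, and the
  generator's timetable stands in for them in all tests.
* Benchmark-scale reproduction (the deposited ~60-hour recordings)
  requires downloading the original datasets; the package reads them
  (TIFF + CSV) but no test depends on them.
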