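---
title: "Parsing and visualizing gaze behavior: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing and visualizing gaze behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeparse)
```

## What this package models

Screen-based eye trackers deliver a stream of gaze positions at 40–500 Hz.
Almost every analysis starts by parsing that stream into oculomotor events:
*fixations* (the eye holding still on a region of interest), *saccades*
(ballistic jumps between fixations), and *smooth pursuit* (slow tracking of
a moving target at roughly 10–30 deg/s). Because pursuit velocities overlap
those of slow saccades, single-threshold parsers are brittle, and because
fixation and pursuit are both acts of holding a target on the fovea, this
package also supports a two-class *behavioral* taxonomy: **stare**
(fixation + pursuit) versus **move** (saccade-like repositioning).

Five things live here, each its own module surface:

1. a data model and preprocessing (`gaze_recording`, pixel↔degree
   conversion, binocular-dropout removal);
2. four classical detectors — I-VT, I-DT, DBSCAN with IQR-selected epsilon,
   and I-VDT;
3. a behavior-based classifier: gaze windows rasterized to grayscale images
   and fed to small convolutional networks;
4. three renderers at increasing abstraction: scanpath, time-layered
   abstract movement visualization, and fixation-count heatmap;
5. evaluation metrics (FQnS, FQlS, pursuit position/velocity scores,
   range-coefficient sweeps, per-class sample-level F1) and a seeded
   oculomotor simulator that makes all of the above testable without any
   recorded data.

## Coordinate and velocity conventions

Pixels have their origin at the screen's top-left corner; degrees are
visual angle about the screen center, computed per axis with the
flat-screen tangent approximation `deg = atan(offset_mm / distance_mm)`.
This is invertible over the whole screen and accurate to well under a
percent at the eccentricities the built-in tasks use. Timestamps are
milliseconds; velocities are two-point backward differences in deg/s, with
the first sample's velocity defined as 0 (so a recording can never open
with a saccade sample). No velocity smoothing is applied — the detectors
here are deliberately the textbook single-pass forms, because parameter
*sensitivity* of those forms is part of what the toolkit is for.

## The four detectors

**I-VT** (`ivt`). One parameter `v_T`: a sample is fixation iff its
velocity is below `v_T`. Runs of equal labels become segments. No minimum
duration is imposed, so near-threshold "blips" survive — that is
intentional; `merge_fixations()` is the explicit post-hoc aggregation
utility (off by default) that joins fixation segments whose centroids are
within 2 degrees and whose gap is at most 500 ms, which is also how the
package counts distinct dwell *regions* when validating parameter
recovery.

**I-DT** (`idt`). Parameters: dispersion bound `D_T` (as
`(max x − min x) + (max y − min y)`) and minimum duration `dur_T`. The
window-growth form is used: seed a window covering `dur_T`; if its
dispersion is within `D_T`, grow it maximally and emit; otherwise slide the
start by one sample. Each grown window is emitted as its **own** segment —
back-to-back windows are not merged, so every reported fixation
individually satisfies both bounds (a run-length merge would silently
violate the dispersion bound).

**DBSCAN with IQR** (`dbscan_iqr`). Density clustering over
`(x, y, w · t_scaled)` where time is min-max scaled to the spatial extent
of the data and weighted by `time_weight`. Epsilon defaults to the third
quartile (linear interpolation between order statistics) of the distances
from each sample to the centroid of all samples (`dbscan_eps_iqr`). A
sample is core when at least `min_points` samples (itself included) fall
within epsilon; clusters are connected components of core points, numbered
chronologically; a border point joins its lowest-index core neighbor.
Segments split at every change of cluster id, so two clusters adjacent in
time remain distinct events.

One honest caveat, discovered while validating on the simulator and worth
knowing before trusting the automatic epsilon: on stimulus layouts whose
dwell regions ring the screen center (the 4-corner box task is the extreme
case), *every* sample is nearly equidistant from the global centroid, so
the Q3 rule returns a radius on the order of the layout itself and the
clustering collapses to one cluster. The rule behaves sensibly when gaze
mass is concentrated around one dominant region. For multi-target tasks
the recommended parameterization therefore carries an explicit foveal-scale
`eps = 1.5` degrees (the spec of `DetectorParams` provides exactly this
override), and `recommended_params()` documents the reason.

**I-VDT** (`ivdt`). Two stages: samples at or above `v_T` are saccades;
each below-threshold run is then split by a growing dispersion window (the
I-DT rule with a 100 ms candidate span, an internal constant `min_fix_ms`):
windows within `D_T` become fixations, non-qualifying samples become smooth
pursuit. Single-sample fixation/pursuit runs are absorbed into an adjacent
non-saccade segment (previous preferred) so non-saccade events span at
least two samples. The 100 ms span is the canonical minimum fixation
duration; at 30 deg/s a 100 ms window sweeps 3 degrees, safely above
`D_T = 1.5`, which is what makes the fixation/pursuit split work.

Recommended defaults (`recommended_params()`): `v_T = 50` deg/s (well above
fixational noise including microsaccades, well below saccadic peaks),
`D_T = 2` with `dur_T = 100` ms for I-DT, `min_points = 5`,
`time_weight = 5`, `eps = 1.5` for DBSCAN, and `v_T = 50`, `D_T = 1.5` for
I-VDT.

## Behavior windows and the stare/move networks

`extract_window()` renders, for each sample, the trailing `history_n`
samples into a square raster centered on the current sample: 32 × 32
degrees (wide enough that a 30 deg/s pursuit trail at 200 ms of history
stays inside), 64 × 64 pixels (1 px = 0.5 degrees, resolving foveal
structure), black background, dots drawn oldest-first with linearly fading
opacity `(h + 1 − age)/(h + 1)` and combined by maximum so the newest dot
wins. `history_n` defaults to 8, i.e. 200 ms at 40 Hz. Rasterization is
translation-equivariant by construction, which is precisely why the
classifier can learn *behavior* rather than screen position.

Labels: fixation and smooth pursuit map to stare; saccade and
post-saccadic oscillation map to move; everything else is excluded.
`build_dataset()` balances classes exactly and can serialize PNG + manifest
datasets; `synthetic_behavior_dataset()` is the bundled generator mixing
saccade-rich search-like scripts, pursuit runs, and box-following runs.

Three architectures are implemented from scratch in C++ (im2col + BLAS
GEMM, Adam at 1e-3, batch 64, softmax cross-entropy, single-precision,
seeded and deterministic on a fixed machine):

* `cnn3` — 3 convolutions (3×3; 32/64/128) + 1 max-pool (4×4, placed after
  the first convolution) + 2 fully connected layers, ReLU;
* `alexnet_like` — 5 convolutions (3×3; 16/32/48/48/32) + 3 max-pools +
  3 fully connected layers, ReLU — the largest model;
* `lenet_like` — LeNet-5-style: 2 convolutions (5×5; 6/16) + 2 max-pools +
  3 fully connected layers (120/84/2), sigmoid.

Only layer counts and activations are inherent to these names; kernel
sizes, widths, pooling placement and the optimizer are this package's
design choices, sized so that the capacity ordering AlexNet-like > cnn3 >
LeNet-like holds structurally (the aggressive single 4×4 pool is what keeps
`cnn3` mid-sized). Inputs are `[0, 1]` grayscale; no normalization beyond
that. `classify_recording()` turns per-window predictions into segments,
merging runs shorter than `min_run = 2` samples into the neighboring
majority (ties resolve toward stare, the prior of the taxonomy).

The printed definition of accuracy in the underlying text of this method
contains a typographical slip (its numerator would be the
positive-prediction rate); `accuracy()` implements the standard
`(TP + TN) / total`.

## Visualization

All renderers return RGBA arrays and are deterministic. The **heatmap**
accumulates fixation-sample counts per pixel (attribute `counts` preserves
the pre-smoothing mass — exactly the number of on-canvas fixation samples)
and smooths with a 1-degree Gaussian, the foveal scale. The **scanpath**
draws duration-scaled fixation dots joined in time order, optionally over
raw samples. The **abstract movement** view gives each stare segment its
own heatmap layer colored by time order (perceptually ordered sequential
scale), composites layers oldest-first, then draws movement links on top:
straight strokes whose width tapers linearly from 6 px at the source to
2 px at the destination (the taper encodes direction) and whose color
interpolates from the source layer's color to the destination layer's.
Link anchors are pulled one smoothing bandwidth outward from the layer
centroids along the movement direction so overlapping dwells remain
distinguishable. A constant-width `taper_px = c(w, w)` reproduces the
legacy link style for comparison figures.

## Evaluation metrics

`fqns()` — percentage of stimulus fixation samples for which a detected
fixation exists at that time with centroid within `dist_tol = 1.5` degrees
(mid-foveal) of the stimulus position. The first 200 ms of every stimulus
fixation period are excluded as saccadic latency; a truth-replay detector
therefore scores exactly 100. `fqls()` — mean centroid-to-stimulus
distance over matched samples; a replay detector scores 0. The pursuit
scores count stimulus pursuit samples the detector labels pursuit *and*
tracks within 4 degrees (position variant) or 10 deg/s (velocity variant).
The literature names these scores inconsistently (PQnS in text, PQlS_P/
PQlS_V in figure captions); the package exposes the neutral
`pursuit_scores()$position` / `$velocity` and documents both aliases.

`rc_sweep()` — a detector-parameter sweep indexed by an integer range
coefficient: the swept threshold at coefficient `r` is `C + r·Vi·T`. The
published composition of the rule is ambiguous (the quantity is described
as a threshold value yet plotted as an integer axis); this linear
reconstruction is config-visible, reproduces the base threshold at `r = 1`
when `C = 0` and `Vi·T` equals it, and degenerates to a constant sweep at
`Vi = 0`. F1 is computed per sample, not per matched event — the source
tables state no event-matching tolerance, so the sample-level form is the
only reconstruction that needs no invented parameter.

## The simulator: what it emulates, and what it does not

`simulate_gaze()` drives an idealized eye along a `make_script()` stimulus:

* **Stays**: fixation with three noise processes — sinusoidal tremor
  (0.05 degrees at 90 Hz), drift (0.5 deg/s with a mean-reverting pull of
  1 s time constant, keeping the 95th-percentile radius well inside the
  1–2 degree foveal bound), and microsaccades (1.5/s, 0.3 degrees, 70%
  return bias, spread over ~20 ms so their velocities stay realistic at
  500 Hz).
* **Slow legs (≤ 30 deg/s)**: smooth pursuit at gain 0.95; positional lag
  accumulates and is cleared by catch-up saccades at 2 degrees of lag,
  with main-sequence-style durations `2.2·amplitude + 21` ms.
* **Fast legs**: one ballistic saccade with a symmetric (triangular
  velocity) profile, then fixation on the landing point while the target
  finishes its sweep.
* **Dropouts**: both-eye-invalid samples at rate 1%.

Ground-truth labels follow the *movement within the sampling interval*,
not the phase clock: a sample is a saccade only when the ballistic flight
covers at least half of its interval. (Labeling by phase would mark
samples where the eye provably had not yet moved as saccades — at 40 Hz
roughly a third of the move class — which poisons any behavior classifier
trained on the labels. This is a property of how ground truth should be
defined, not a tuning knob.)

Built-in tasks: the 4-target box-following task (rectangle with 15 / 27.5 /
15 degree spacings, 3 s stays, 0.2 s transitions by default — a value from
the short-transition task family that keeps all legs saccadic; 0.5 s would
put the 15-degree legs exactly at the pursuit boundary) and two 6-point
tasks (up-down and Z-shape, 30 deg/s target, points on a grid spanning 20
degrees — the layout is not prescribed anywhere, so it is a config-visible
choice — with 3 s stops or pass-through).

What the simulator does **not** emulate: binocular vergence and per-eye
geometry, post-saccadic oscillations (the `pso` truth label is accepted
from external annotations but never generated), blink kinematics beyond
dropout gaps, head movement, and tracker-specific filtering. Tests passing
on simulated data therefore certify algorithmic correctness and
calibration, not performance on any particular hardware or observer
population.

## Problem sizes and numerical choices

The test-suite and acceptance-script problem sizes are the package's
chosen defaults for a reproducible desk-scale run: 20 seeded simulations
for parameter recovery, 200 random traces of up to 50 samples for
detector/oracle equivalence, and a balanced 2 × 2500-window dataset at
64 × 64 with 5 training epochs for the network comparison (the
classifier's learning curves flatten well before that on this data).
Degenerate inputs are handled explicitly: recordings of fewer than two
samples refuse velocity-based parsing; coincident points make the IQR
epsilon 0, which `dbscan_iqr` rejects with instructions to pass `eps`;
`cross_entropy()` clips predictions at 1e-12; ties in the stare/move run
merge resolve toward stare. Network training is bit-reproducible for a
fixed seed on one machine (private Mersenne Twister streams for
initialization and shuffling; single-precision BLAS); across BLAS builds
only metric-level, not bit-level, agreement should be expected.

## Known limitations

* The IQR epsilon rule degrades on center-symmetric multi-target layouts
  (see above); supply `eps` explicitly there.
* Sample-level F1 rewards boundary agreement more than event-count
  agreement; detectors that fragment events are penalized only mildly.
* The stare/move networks are trained on simulator output in the bundled
  datasets; transfer to a particular tracker requires retraining on
  windows built from that tracker's recordings (`build_dataset()` accepts
  any recording with per-sample annotations).
* `rc_sweep()`'s linear rule is one reconstruction of an ambiguous
  published formula; sweeps are therefore comparable within this package
  but not necessarily across implementations.
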