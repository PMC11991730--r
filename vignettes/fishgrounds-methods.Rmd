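---
title: "Weakly supervised fishing-ground estimation: models, choices and limits"
author: "fishgrounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised fishing-ground estimation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishgrounds)
```

## The problem

Fishers choose daily fishing grounds partly by reading two-dimensional
sea-surface-temperature (SST) structure — fronts, eddies, the thermal
preference of the target species. `fishgrounds` casts that decision as
*keypoint detection*: the input is one day's gridded SST field, and the
output is a heatmap whose local maxima are candidate fishing grounds.

The difficulty is supervision. Catch logbooks are accurate ("strong"
labels: a CPUE > 0 record pins a real ground) but sparse and *partial* —
unvisited grounds are simply missing. Vessel trajectories (AIS) are
plentiful but only weakly informative: a short or looping day-track
suggests fishing, a long straight transit argues against it, and neither
says anything about catch. The package trains a small convolutional
heatmap regressor in two phases — pre-training on trajectory-derived
heatmaps, fine-tuning on catch-derived heatmaps — and uses a second
small network, the *confidence network*, to down-weight unreliable weak
labels during pre-training.

## Labels and heatmaps

Each record becomes one labeled instance:

| Label    | Rule                                  | Source     |
|----------|---------------------------------------|------------|
| Good     | CPUE > 0                              | catch      |
| Bad      | CPUE = 0                              | catch      |
| Unlikely | daily start–end displacement > 200 km | trajectory |
| Unknown  | displacement ≤ 200 km                 | trajectory |

A trajectory day is represented by its mean daily position (longitudes
unwrapped so the antimeridian is safe), and trajectory instances whose
cell temperature falls outside the 19–26 °C skipjack habitat band — or
sits on a missing (land) cell, which is zero-filled and therefore
outside the band — are discarded. Catch records are trusted as-is.

Ground truth is a three-channel raster (Good, Bad, Unlikely) at the
model's output resolution. A Gaussian kernel
`exp(-||p - p_t||^2 / (2 sigma^2))` with `sigma = 7` heatmap pixels is
placed at each instance; multiple kernels combine by pixelwise maximum,
which keeps every instance's peak at exactly 1 (the property peak
detection relies on). Kernels are truncated at 4 sigma, making "zero
pixel" well defined. Catch days fill Good and Bad and leave Unlikely at
zero; trajectory days put Unknown instances on *both* Good and Bad
(they cannot be told apart) and Unlikely instances on the third
channel. The two heatmap types are never mixed in one training sample.

## The confidence statistic and network

For a day present in both streams, the validity of the weak label is
scored on the Good channel as

    c = 1 - min( w_count * sum_ij ReLU(y_ij - ytilde_ij), 1 ),
    w_count = 1 / (n_nonzero + 1)

where `y` is the catch heatmap, `ytilde` the trajectory heatmap and
`n_nonzero` the weak channel's non-zero pixel count (pixels above 1e-8;
kernel truncation makes this exact). Confidence drops only where catch
evidence lands on weak-label silence — the catch map is assumed to
*under*-cover the true grounds, so extra weak area is free, and the
`w_count` factor actively favours samples with large weak regions. The
statistic is 1 whenever `y <= ytilde` pixelwise, and it is monotone:
non-increasing in each catch pixel, non-decreasing in weak support.

The summation uses the Good channel only: the statistic is defined on a
single 2-D array, and Good is the channel the evaluation scores. This
was a genuinely open reading (one channel vs all three); the
single-channel reading keeps the statistic interpretable as "unmatched
catch mass" and is what the package implements.

The confidence network takes the (downsampled, per-map standardized)
SST field and the 3-channel weak heatmap through two conv layers per
branch (3×3, stride 1, zero padding, ReLU), flattens, concatenates, and
ends in a ReLU dense layer and one linear logit. Branch widths (8, 16),
head width 64 — the topology is fixed by the design, the widths were
not printed anywhere and are configurable. It is trained as soft-label
binary classification: `-(c log σ(z) + (1-c) log(1-σ(z)))` with Adam,
model selection at the lowest validation loss; the sigmoid is applied
only at inference.

## Confidence-weighted pre-training

The target network update on a weak batch is

    w <- w - (eta / b) * sum_i c_i * grad L(f(x_i), ytilde_i)

with `c_i` the *frozen* confidence net's inference output for sample
`i`; no gradient reaches the confidence net. With all `c_i = 1` this is
exactly an unweighted step (bitwise, in the implementation). The update
is written for SGD; with the default Adam optimizer the confidence
weight multiplies each sample's loss (hence its gradient) and Adam then
preconditions the weighted sum — the closest faithful composition. An
exact-SGD mode exists and is what the equivalence tests exercise.

One textual ambiguity had to be resolved: the methods description and
the training figure put the confidence weighting in *pre-training*,
while one sentence in the experimental-design prose says the confidence
output guided *fine-tuning*. The package follows the methods reading
(weighting in pre-training); `runExperiment(confidencePhase =
"finetune")` switches to the alternative.

## Target network and losses

The heatmap regressor is backbone-agnostic; the bundled `tiny_cnn` is
four 3×3 conv-ReLU blocks with 2×2 max-pool downsampling (stride 1, 2
or 4) and a linear 1×1 head — about 3.6k parameters at the defaults,
trainable on one CPU in seconds. The original work used a lightweight
pose-estimation backbone purely for feasibility; nothing in the method
depends on it, so the package ships the smallest architecture that
exercises every mechanism and accepts plug-in backbones honoring the
same contract. The head carries no final nonlinearity (targets live in
[0, 1] but raw regression is the pose-estimation convention);
predictions are clipped at zero only for peak detection. Inputs are
standardized per map over non-missing cells by default (raw °C behind a
flag).

Losses: `L2 = 1/2 Σ (ŷ - y)²`; the one-sided hinge `LH = Σ ReLU(y - ŷ)`
penalizes only under-detection; and the blend `L = α L2 + (1-α) LH`.
Small `α` provokes more detections — at the cost of precision, which is
why L2 remains the default.

## Evaluation

Only the Good channel is scored. Peaks are pixels that attain the
maximum of their 8×8 sliding window (rows −4…+3 around the pixel,
clipped at borders) and exceed a height threshold (default 0.1 — the
bare max filter would emit "peaks" on near-zero noise; the value is
configurable and always reported). Among *exact* ties, if one tied
candidate lies inside the other's window only the first in row-major
order is kept; tied candidates farther apart are genuinely distinct
peaks. An exhaustive sliding-window oracle in the test suite pins these
semantics.

A peak is a true positive when its great-circle distance to the nearest
ground-truth point is below 200 km — the distance a vessel at 14 knots
(26 km/h) covers in roughly eight hours, i.e. "reachable today".
Distances are haversine on a 6371-km sphere; the spherical error is
orders of magnitude below the decision threshold, so ellipsoidal
geodesy would buy nothing. Matching is many-to-many (the criterion is
purely the distance; a greedy one-to-one mode exists as a sensitivity
flag), precision/recall are micro-averaged over pooled test-day
tallies, and `F1 = 2PR/(P+R)` with the 0 convention when both vanish.
Peak coordinates are taken at heatmap-pixel centers; sub-pixel
refinement is pointless against a 200-km radius and σ = 7 kernels.

The study frame spans 130°E–150°W, crossing the antimeridian, so all
longitude arithmetic is modular: longitudes are stored in (−180, 180],
column offsets computed mod 360, and trajectory means computed on
unwrapped longitudes. Grid cells are treated as *centers* (the
convention was unstated; centers make the point→cell→point round trip
an identity, which the tests enforce on every cell of the full frame).

## The synthetic world

No real SST, logbook or AIS data ship with the package. The simulator
generates what the method needs structurally:

* **SST** — a north–south gradient (14 °C at the north edge, 29 °C at
  the south, so the 19–26 °C band is a mid-latitude strip), plus
  Gaussian-smoothed noise (length scale 3 cells, amplitude 0.8 °C) and
  4 Gaussian eddies per day (±2.5 °C, radius ~4 cells); a 3-column land
  stripe is masked and zero-filled. Default frame: 40×64 cells at
  0.25°, i.e. 10°×16° of ocean.
* **True grounds** — 3 cells/day sampled from the habitat band with
  probability ∝ local SST-gradient magnitude (grounds sit on fronts and
  eddy rims), with a 300-km pairwise exclusion: grounds closer than the
  200-km scoring radius are indistinguishable to the metric, so a day's
  grounds are kept distinct locations.
* **Vessels** — 6 per day; with probability 0.3 a vessel transits
  (straight hourly track, displacement > 200 km → Unlikely); otherwise
  it loiters near a ground whose centre is jittered by a 60-km
  positional noise (→ Unknown, sometimes off-ground: that *is* the
  label noise the confidence net must learn to flag).
* **Catch** — each true ground is logged with probability 0.6 as a
  CPUE > 0 record (log-normal magnitude; only the >0 dichotomy
  matters), and loitering vessels file zero-CPUE visits with
  probability 0.3.

Splits are disjoint day ranges: 120 pre-training (trajectory) days, 40
fine-tuning (catch) days, 20 test days; pre-training days keep their
catch logs so confidence targets come from genuinely paired days.
Everything is a deterministic function of the world seed.

What the simulator does *not* emulate: ocean dynamics (advection,
fronts with physical structure), fish population dynamics, seasonal
cycles, vessel-behaviour idiosyncrasies, or the severe class imbalance
and observation bias of real logbooks. Passing tests on this world show
the machinery is internally consistent and that the training signal
flows as designed — not that the method attains any particular skill on
real oceans.

## Desk-scale training settings

The reference hyperparameters (Adam; learning rates 4e-5 target / 1e-5
confidence; batch 16; 100 pre-training, 33 fine-tuning, 19 confidence
epochs) are the `phaseConfig()` defaults. They are sized for thousands
of real training days; on the 40×64 synthetic world with 120 weak days
they would barely move the weights. `deskPhases()` is the package's
scaled-down preset — Adam at 1e-3, 10/10/8 epochs — chosen so one
four-arm comparison runs in well under a minute and a 20-world
replication in about ten minutes on one CPU. Validation splits are by
whole days (0.2), target-network selection is by validation F1 in
fine-tuning (ties to the later epoch, so equal-F1 training is not
discarded) and by validation loss elsewhere.

## The comparison arms

`runExperiment()` wires four arms: `catch_only` (fine-tuning only),
`fine_tuning_legacy` (pre-training on per-day heatmaps that merge
trajectory and catch instances by channel-wise maximum — an
approximation of the earlier two-source recipe, whose exact heatmap
scheme is not recoverable from the available description),
`w_o_confidence` (plain weak pre-training), and `w_confidence` (the
full method). `compareArms()` replicates the comparison across seeded
worlds and reports medians; on the default conditions the expected
qualitative ordering is `w_confidence ≥ w_o_confidence ≥ catch_only`
in median F1, with both trajectory-using arms emitting more peaks than
`catch_only` — the under-detection problem that motivates weak
supervision in the first place.

## Numerical choices and degenerate inputs

* Convolutions run via precomputed im2col index gathers and BLAS
  matmuls; a batched row-stacked path computes whole-batch gradients in
  single BLAS calls and is tested to equal the per-sample path to
  machine precision. Gradients of every layer are verified against
  central finite differences.
* Half-cell coordinate ties round toward the lower index (documented,
  tested). Empty instance sets yield all-zero heatmaps; empty peak sets
  score precision = recall = 0 by convention; an empty habitat band
  yields a day without grounds.
* Training is bit-for-bit reproducible under a fixed seed (data
  generation, splits, init, shuffling all hang off it).

## Known limitations

* The hinge-loss ablation's "more peaks" direction, clear at the scale
  of the original study, is noisy at desk scale: it holds on the
  default world but can reverse on individual seeds. The package states
  it as a single-world, converged-fine-tuning comparison.
* The legacy arm is an approximation (see above), flagged as such.
* The confidence net at the default widths carries ~1.3M parameters —
  dominated by the flatten–dense junction — which is heavy relative to
  the 3.6k-parameter detector; widths are configurable downward for
  constrained runs.
* Real-data I/O is plain-text rasters and CSVs; NetCDF ingestion would
  be the natural extension for NOAA-style archives.
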