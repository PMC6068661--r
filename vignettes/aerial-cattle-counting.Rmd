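---
title: "Counting cattle in nadir UAV imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cattle in nadir UAV imagery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A multirotor flying a survey pattern over pasture carries a camera pointed
straight down. The task is to count the cattle visible in each video frame.
Animals seen from above are small, compact blobs of fairly uniform coat
colour on a textured pasture background, accompanied by an offset shadow
that is easily mistaken for a second animal. `cattlescan` implements the
complete per-frame pipeline: a two-class convolutional tile classifier, a
three-scale sliding-window scan producing a probability lattice, a
neighborhood boosting step, an ad hoc threshold, and connected-component
counting. Because flight footage of this kind is rarely shareable, the
package also ships a seeded synthetic scene generator that provides
ground-truthed imagery for training and for every test.

## The detection model

**Tile classifier.** The classifier consumes 64x64 RGB tiles and emits two
softmax probabilities, target and background. The architecture is
`64x64-18C7-MP4-96C5-MP2-nL-2`: 18 convolutional filters of 7x7, 4x4 max
pooling, 96 filters of 5x5, 2x2 max pooling, then a fully connected MLP
whose single hidden layer has `2n + 1` units, where `n` is the flattened
feature count entering the MLP. Under valid convolution (stride 1, no
padding) and floor-division pooling the spatial sizes run
64 → 58 → 14 → 10 → 5, so `n = 96 · 5 · 5 = 2400` and the hidden layer has
4801 units. `cnn_spec()` derives and prints these numbers; the package
always sizes the head from the `n` its own convolution convention
produces. ReLU follows each convolution and the hidden layer; the hidden
activation is a free choice here and ReLU was picked for symmetry with the
convolutional stages.

**Training.** Minibatch SGD minimises the mean squared error between the
softmax outputs and one-hot labels. Three conditioning choices matter and
are deliberate:

* inputs are normalised to `x/255 - 0.5` (centred). With all-positive
  inputs this criterion has a strong saddle at the constant base-rate
  predictor (loss 0.222 for a 1:2 class mix); in our experiments plain
  SGD never escaped it at any learning rate between 0.01 and 1.0, while
  centring the inputs lets the same architecture train through;
* classical momentum (default 0.9) makes that escape reliable: without
  it, whether training leaves the saddle within the epoch budget depends
  visibly on the initialisation seed, which no reproducible pipeline
  should accept;
* the default learning rate is 0.02 with momentum 0.9 (an effective step
  comparable to plain SGD at 0.1–0.2). MSE-through-softmax gradients
  carry an extra factor of roughly `p(1-p)` compared to cross-entropy,
  so rates that would be aggressive elsewhere are moderate here.

Both are exposed in `training_config()`, as is an optional
`balance_classes` flag: the tile recipe yields twice as many background
as target tiles, and under the MSE criterion that imbalance depresses
borderline target windows below the boosting gate of 1/2 — each animal
then lights only its single nearest grid cell and falls under the
detection threshold. Seeded per-epoch oversampling of the minority class
(the dataset itself keeps the canonical 1:2 composition) removes most of
that failure mode, and the study-scale runs enable it. Weights start from
a seeded uniform distribution scaled by fan-in; biases start at zero.
Every shuffle, initialisation and augmentation draw descends from one
integer seed, so training is bit-reproducible.

**Scanning.** The mid-range window size is derived trigonometrically from
the flight geometry: a frame at altitude `h` with horizontal field of view
`fov` images a ground width of `2 h tan(fov/2)`, so a 2.5 m animal spans
`2.5 · image_width / (2 h tan(fov/2))` pixels. Two satellite scales at 85%
and 115% of that size catch smaller and larger animals. Windows are
centre-aligned across scales on a regular lattice (default stride: half
the mid window, "adjacent and overlapping"), clipped to the frame,
resampled bilinearly to 64x64 and classified; the target probabilities
form the lattice `L[x, y, s]`.

**Boosting, threshold, counting.** Each lattice cell is boosted by
summing, over its 3x3 spatial neighborhood and all three scales, the
values that reach 1/2 (weaker readings and out-of-grid neighbours
contribute zero), giving `B[x, y]` bounded by 27. The gate is applied per
term: applying it to the whole sum instead would make the piecewise
definition vacuous. A threshold then quantizes `B` into a binary mask.
Isolated single-window activations — the dominant false-positive mode —
cannot reach the default threshold of 4.5, which demands several mutually
reinforcing readings; genuine animals light up neighbouring windows at
several scales. Finally, 8-connected component labeling (diagonal
activations from one animal merge) produces the per-frame count and
per-component boxes. The threshold is application-specific by design;
`tune_threshold()` sweeps candidates against ground-truthed validation
scenes.

One boundary convention is worth noting: `boost()` accumulates its 27
gated terms in a fixed `(i, j, s)` order so that the vectorised
implementation is bit-identical to a literal scalar transcription of the
triple sum — floating-point addition is not associative, and the tests
hold the implementation to exact equality against an independent
brute-force oracle.

## The synthetic data

`render_sprite_bank()` and `render_scene()` emulate the structure of tiles
hand-cut from survey footage:

* **animals** are procedurally drawn top-down cattle — an ellipsoidal body
  with a head lobe, random orientation, coats drawn from a
  brown/dark/black/white/tan palette — on pasture, with their own offset
  shadow;
* **shadows** (dark, sheared silhouettes on pasture) are a separate source
  class used as hard negatives, because a shadow looks like an animal to
  any brightness-based detector; the classifier has only two output
  classes, so shadow tiles are labeled background;
* **backgrounds** are seasonally coloured pasture textures ("green" or
  "dry"), a base hue modulated by a smooth coarse field plus per-pixel
  noise.

Tiles are drawn at a native resolution of about 32 px (a cow spans about
20 px, as seen from survey altitude) and upsampled to 64x64, so training
tiles pass through the same bilinear resampling as detection windows.
Three jitters in the generator are deliberately wide, and each closes an
observed failure mode of the detector:

* **native resolution** varies by 0.8–1.25 per tile, emulating
  recordings at different heights. The three window scales resample
  their crops by factors of 1.73–2.37; with a fixed 2x training factor
  the classifier learned the resampling signature instead of the animal
  and ignored the satellite scales entirely;
* **position** varies by ±38% of the patch, so windows with the animal
  well off-centre — even partially outside — still classify as target.
  The boosting stage only clears its threshold when a neighborhood of
  windows fires; a perfectly centred-tile classifier lights exactly one
  grid cell per animal (a boosted score of about 3, below the 4.5
  threshold) whenever the animal lands on a grid centre;
* **size** varies by 0.7–1.3 around the nominal 62% of the patch.

Scene placement is rejection sampling with a cap of 1000 attempts per
sprite; bounding boxes may not overlap and centres must be at least
`min_separation` apart (default 4.5 body lengths). A failed layout is
discarded and redrawn up to 200 times before the generator reports a
placement error. The separation default reflects the detector's geometry:
a firing region dilates by one grid cell in the boosting step, so blobs
from animals closer than about three window widths can touch under
8-connectivity and merge into one component. Counting overlapping or
tightly clustered groups is out of scope, as is cross-frame tracking of
animals re-entering the field of view.

What the generator does *not* emulate: perspective distortion away from
nadir, motion blur, video compression, terrain relief, occlusion, and the
long-tailed appearance variation of real herds. Passing the synthetic
recovery tests therefore demonstrates that the pipeline's machinery is
correct and well-calibrated for its geometry — not that the shipped
defaults would transfer to real footage without retraining on real tiles.

## The augmentation recipe and split

Each source image yields its three 90-degree rotations (exact pixel
permutations — interpolation would blur the one augmentation that can be
lossless), and each of the four resulting images yields two "slight"
perspective deformations: the four corners are jittered independently by
up to 10% of the side and the image is resampled under the induced
homography. The factor of two is the only one consistent with a
400 → 1200 expansion per class; the jitter bound is configurable because
"slight" is not otherwise quantified. A class of 100 source images thus
becomes 400, then 1200 tiles.

`split_dataset()` shuffles and splits stratified by label. The overall
train size is `round(ratio · n)` with stratum sizes allocated by largest
remainder, so each stratum's proportion is within one tile of the ratio.
The default ratio of 0.8 reproduces the canonical 13,520 → 10,816 + 2,704
division exactly.

## Numerical and degenerate-input conventions

* Bilinear sampling clamps to pixel centres, so border lookups replicate
  edge pixels; perspective warps use the same convention rather than
  introducing black borders.
* Max pooling breaks ties toward the earliest window offset,
  deterministically; class prediction breaks probability ties toward
  background.
* `softmax()` subtracts the maximum before exponentiating (shift
  invariance doubles as overflow protection at inputs of magnitude 1000).
* Empty masks label zero components; empty scenes are pure background
  with count 0; a training set with one class present is rejected as
  degenerate rather than silently fit.
* The altitude-derived window is clamped below at 8 px and rejected if it
  exceeds the frame ("altitude too low").
* Checkpoints store weights and the loss history as little-endian binary
  doubles with a JSON header, so a reloaded network reproduces
  predictions bit-for-bit.

## Problem sizes used by the tests and the acceptance script

The shipped demonstrations are sized for a desk machine: a sprite bank of
32 images per class expands to 1152 tiles (922 train / 230 test), the
classifier trains for 20 balanced epochs (learning rate 0.02, momentum
0.9, batch 64), and detection runs over 50
synthetic scenes containing 0–9 animals, 256x256 px with 320x320 px for
the most crowded frames so that nine animals fit at the default
separation (a 15x15 or 19x19 grid of centres at stride 16, three scales,
675–1083 window classifications per frame). These sizes were chosen as
the smallest at which tile accuracy saturates and count recovery is
stable; all of them are parameters, and nothing in the implementation
depends on them.

## Known limitations

* The counter resolves well-separated animals only; clustered groups
  merge into one component (`min_separation` documents the geometry).
* The probability lattice inherits the grid stride's localisation limit:
  component centroids are accurate to about one stride.
* PNG is the supported frame format; video must be pre-extracted to
  frames (at the survey's 2 frames/s, a 35 s pass contributes 70 frames).
* The classifier is only as good as its tiles; the shipped sprite bank is
  a structural stand-in for hand-cut footage tiles, and real deployments
  should rebuild the dataset from their own recordings.
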