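---
title: "Label-free viability estimation with dual count-regression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free viability estimation with dual count-regression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cytotoxicity assays quantify the viability of a culture — the percentage of
live cells among all cells — almost always with membrane-exclusion dyes
(trypan blue and relatives) or biochemical assays. Both chemistries are
themselves toxic, rupture dying cells, and preclude monitoring the *same*
culture over time. `brightcount` implements a purely computational
alternative: viability estimated from unstained brightfield phase-contrast
images alone, exploiting the morphological signature of cell death. Dying
adherent cells detach, round up, darken, and acquire a bright refractile
halo; live attached cells stay elongated, slightly lighter than background,
and halo-free.

## The method

Two independent convolutional count-regression networks operate on
224 × 224 tiles cut from each frame:

* the **total-cell counter** sees contrast-stretched tiles (Enhancement 1)
  and predicts the number of cells of any state in the tile;
* the **dead-cell counter** sees Sobel-gradient-magnitude tiles
  (Enhancement 2) — dead cells, ringed by high-contrast halos around dark
  cores, survive this filter as bright rings/dots while the flat background
  and the low-contrast live cells are suppressed — and predicts the number
  of dead cells.

Counts are summed over a frame's tiles and combined into

$$\hat V = 100\,\Bigl(1 - \frac{\hat D}{\hat T}\Bigr),$$

while the annotation-derived truth is $V = 100\,L/T$. The two formulas
coincide whenever counts are exact, because total = live + dead. Crucially,
no localisation is attempted: a viability percentage needs only the two
counts, so each network is a backbone ending in global average pooling and a
single-neuron fully connected layer emitting one scalar per tile. The same
architecture with the image-level viability percentage as the tile target
gives the `single_direct` baseline variant; running the two counters on
unenhanced tiles gives the `dual_plain` ablation. `run_config(mode = ...)`
switches between the three.

### Error propagation

The decomposition makes the failure directions transparent: if the total
counter over-counts ($\hat T \ge T$) while the dead counter under-counts
($\hat D \le D$), the predicted viability can only exceed the truth. This is
an exact algebraic fact (tested on 1,000 random count triples), and the
mechanism behind the systematic viability over-prediction this family of
models shows: contrast stretching amplifies cell-like background artifacts
(inflating $\hat T$) and edge enhancement under-represents the smallest
apoptotic bodies (deflating $\hat D$).

## Tiling and labels

A $W \times H$ frame is cut into a non-overlapping
$\lfloor W/224\rfloor \times \lfloor H/224\rfloor$ grid anchored at the
origin, discarding right/bottom remainders — the only convention consistent
with the printed arithmetic (2048 × 1536 → 9 × 6 = 54 tiles; 21 frames →
1134; 4 → 216). Tile membership of a point label uses half-open intervals
($i = \lfloor x/224\rfloor$), a deterministic tie-break for points on shared
edges; margin points are dropped and counted. Labels are applied to the
*raw* frames and only then are images enhanced, so both counters share one
ground truth.

Annotations travel as VGG Image Annotator (VIA) point-label JSON: each cell
is one point region (`cx`, `cy`) with a live/dead class attribute. The
reader is liberal (flat export or VIA2 project format; configurable class
attribute; a caller-supplied class for single-class files, which is how
live-only / dead-only labelling sessions are stored), the writer emits the
flat export. Duplicate coordinates are kept but flagged, since independent
live and dead labelling passes can in principle mark the same cell twice.

## The enhancements, concretely

**Enhancement 1** is described functionally in the source material
(suppress background noise, raise cell/background contrast) but not
algorithmically; `brightcount` concretises it as a percentile linear
stretch: the `p_low` (default 1) percentile maps to 0, `p_high` (default
99) to 255, clamped and monotone. The percentiles are computed per frame
(stable statistics) before tiling. This is an interpretation, and the
`enhancement_spec()` interface deliberately keeps alternatives pluggable.

**Enhancement 2** is the classic 3 × 3 Sobel pair; the gradient magnitude
$\sqrt{G_x^2 + G_y^2}$ is computed with reflect (edge-mirroring) padding and
min–max rescaled to 0..255. The rescale is per tile by default
(`enhance_tiles()`), mirroring filters applied to tiles; a per-frame
variant is a one-liner (`enhance_sobel()` on the frame before tiling).
Degenerate inputs have documented rules: a constant image stretches to all
zeros with a warning, and a constant gradient rescales to zeros.

## The counter networks

No deep-learning framework is assumed: the conv forward/backward passes are
implemented in compiled code (im2col + GEMM via RcppArmadillo) with the
orchestration, ReLU, global average pooling, the one-neuron head, and Adam
in R. The default backbone is deliberately small — a 2× average-pooling
stem followed by four stride-2 3 × 3 conv + ReLU stages of 8/16/32/32
channels (≈ 19k parameters) — sized so that a full train/evaluate cycle
runs in minutes on one CPU core. The published approach fine-tuned an
ImageNet-pretrained EfficientNet; the contribution being reproduced is the
regression-head-plus-enhancement pairing rather than backbone capacity, so
transfer learning is exposed only as an option (`pretrained_init` with a
local weights file; nothing is ever downloaded) and the three variants
always share one architecture.

Training choices, all surfaced in `training_config()`:

* **loss** — mean squared error on the scalar output; the canonical
  regression choice (the source material names none);
* **optimizer** — Adam, default learning rate 5e-3, batch size 4, 10
  epochs; defaults fixed by a documented small-budget calibration run on
  synthetic corpora;
* **head-bias initialisation** to the mean training target, a standard
  regression shortcut that removes the slow "find the offset" phase;
* **augmentation** — the eight dihedral flips/rotations, which preserve
  counts; on by default;
* **freezing** — never; all weights always train.

Count predictions are clamped at zero; the direct-viability target at
0..100. Determinism: fixed seeds give identical initial weights, shuffles
and augmentations, hence bit-identical loss histories and predictions
(single-threaded BLAS assumed; no other nondeterminism sources exist in the
implementation).

## The synthetic scene generator

No imagery was deposited with the source study, so the package ships a
generator whose scenes make every downstream stage testable with known
ground truth. It emulates exactly the morphological contrasts the method
exploits:

* **live cells**: elongated ellipses (semi-major axis 12–24 px, minor/major
  ratio 0.3–0.6, random orientation), +12 intensity over background — low
  contrast, no halo;
* **dead cells**: circles with a dark core (−55) and a bright halo annulus
  (3 px, +30). Radii are *bimodal*: a small apoptotic mode (3–6 px, weight
  0.4) and a large necrotic mode (9–16 px), so the "very small dead cells
  are missed" failure mode is reproducible;
* **artifacts**: faint blobs (+6) statistically between live cells and
  background — the mechanism behind total-counter over-prediction;
* **background**: flat field (mean 130) plus additive Gaussian noise
  (sd 8), clamped to 8 bits.

All geometry defaults are implementer-chosen for a 2048 × 1536 frame at
roughly 10×-objective scale (an MDCK-like epithelial cell of 15–25 µm spans
roughly 25–50 px there); none are measured values from the source study,
which gives no pixel sizes or per-frame densities. Default density is 350
cells/frame (260 live + 90 dead, ≈ 6–7 cells per tile), object centres are
rejection-sampled with a 26 px minimum separation, and every scene is
bit-reproducible from its seed. What the generator does **not** emulate:
phase-contrast optics (shade-off, partial halos on live cells), cell
clumping and confluent sheets, debris fields, focus drift, illumination
gradients. Passing tests on these scenes therefore demonstrate the
*pipeline's* correctness and the *method's* behaviour under controlled
morphology — not performance on real microscopy.

A rendered counterpart of the morphological separability assumption is
asserted in the test suite: over seeded scenes, the mean Sobel magnitude
around dead-cell centres exceeds that around live-cell centres — this is
precisely the property Enhancement 2 exploits.

## Study conditions used by the tests and the acceptance script

The count-recovery evaluation generates 20 training and 5 validation frames
at the published 2048 × 1536 geometry (1080/270 tiles), truth viability
drawn uniformly from 13–97%, and trains both counters for 10 epochs with
the defaults above (≈ 2 minutes per counter on one CPU core). Acceptance
asks for held-out per-tile MAE ≤ 2.0 cells per counter and a mean per-image
viability error ≤ 10 percentage points; the same corpus also trains the
`single_direct` baseline for the variant comparison, which is reported (and
warned on inversion) rather than hard-asserted, being a stochastic ordering.
The unit-test suite uses much smaller frames (224–672 px) throughout.

## Degenerate inputs and numerical conventions

* `combine_viability(0, 0)` → `NA` (undefined-viability sentinel, logged);
  `T = 0, D > 0` → 0% with a warning; `D > T` → clamped to 0% with a
  warning. All reported viabilities lie in [0, 100] or are the sentinel.
* Single-image evaluations flag the predicted-vs-truth regression as
  undefined instead of fitting two points.
* Coordinates are 0-based (x = column, y = row, matching VIA `cx`/`cy`);
  fractional coordinates round half-up on read.
* Greyscale conversion uses BT.601 luminance weights.
* The evaluation's line fit is ordinary unweighted least squares of
  predicted on truth.

## Known limitations

* The backbone is desk-scale by design; absolute accuracies on real
  microscopy would require the pretrained-backbone option plus real
  labelled frames.
* Enhancement 1 is one concretisation of a verbally described filter.
* The generator's realism limits (above) mean synthetic accuracy numbers
  should not be quoted as expected real-data performance.
* Only PNG image IO is bundled; convert JPEG frames before use.
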