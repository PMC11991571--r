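---
title: "Wave-Net raft-aquaculture segmentation: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-Net raft-aquaculture segmentation: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveseg)
```

## The problem

Marine raft aquaculture — longlines, rafts and cages laid out in regular
rectangular arrays — is routinely mapped from spaceborne synthetic aperture
radar (SAR), which observes through cloud and at night. Two properties of SAR
imagery make pixel-level segmentation of these structures hard. First,
coherent imaging produces *speckle*: a granular, multiplicative noise arising
from the interference of returns from many random scatterers within a
resolution cell. Second, raft fields occur at several characteristic scales
in the same scene, and plain encoder–decoder networks tend to blur or
wrongly merge their boundaries.

`waveseg` implements an end-to-end pipeline for this problem: a synthetic
speckled-scene simulator with exact ground truth, Refined Lee despeckling,
tiling/augmentation/splitting, the wave-shaped segmentation network
(Wave-Net) itself with native reverse-mode differentiation and Adam, and a
metrics/stitching evaluation kit.

## The Wave-Net model

The network is a cascade of `L` *V-shaped* subnetworks (feature aggregation)
followed by `L` *Λ-shaped* subnetworks (feature dispersion), with 2×2
max-pooling between aggregation stages and bilinear 2× up-sampling between
dispersion stages. `L` is selected from the tile size
(`select_architecture()`): tiles in [300, 400) use `L = 3`, [400, 500) use
`L = 4`, and [500, 600] use `L = 5`.

Every convolution is a *DWC unit*: a depthwise 3×3 convolution (padding 1),
a pointwise 1×1 channel projection, batch normalization and the SiLU
activation `x·sigmoid(x)`.

* A **V subnet** of height `h` runs `h−1` encode steps (DWC unit, then 2×2
  max-pool), a bottom DWC unit, and `h−1` decode steps (bilinear 2×
  up-sample, then a DWC unit applied to the concatenation with the
  identically sized encoder feature). Input and output resolutions are
  equal.
* A **Λ subnet** mirrors it: `h−1` expand steps (up-sample then DWC unit)
  followed by `h−1` reduce steps (DWC unit then max-pool), with
  identical-scale concatenation between the expand and reduce paths.
* Both carry a **residual connection** from block input to block output
  (identity when channel counts match, a 1×1 projection otherwise),
  removable via `ablate_residuals()` for the ablation experiment.

With the default depth schedules — V heights `L+1, L, …, 2` by stage and Λ
heights mirrored so that the deepest stage gets depth `L+1` first — every V
subnet bottoms out at `H/2^L` and every Λ subnet crests at `2H`: the feature
resolution traces a wave across the whole network, which is what the
architecture is named after. The depth ordering of the Λ part relative to
resolution is genuinely underdetermined by its verbal description
("decreases gradually" along the processing order); we adopt the
deepest-stage-first mirror because it is the only assignment that gives all
stages a common trough and a common crest, and we expose both height vectors
in `wavenet_config()` so other readings are one argument away.

Stage `i`'s aggregation output is concatenated with the same-resolution
dispersion output, passed through a 1×1 convolution + sigmoid head, and
bilinearly up-sampled to the input size; together with a full-resolution
head on the final dispersion output this yields `S = L + 1` side probability
maps (four at the reference depth `L = 3`). A final 1×1 convolution over the
concatenated side maps, through a sigmoid, gives the fused map used for
prediction.

Channel schedule defaults to `C0·2^(i−1)` capped at `8·C0` with `C0 = 32`;
the cap keeps the `L = 5` variant from doubling indefinitely. `C0` is not
prescribed by the architecture description; 32 keeps the `L = 3` model in
the few-hundred-thousand-parameter range.

### Loss

Training minimizes the multi-scale binary cross-entropy: the sum over side
maps of the pixel-mean BCE against the binary mask, probabilities clamped to
`[1e−7, 1 − 1e−7]` before the logarithm. `multiscale_bce()` computes exactly
the `S`-term side-output sum (four BCE terms at `L = 3`). The fused head
sits *after* the side outputs, so it would receive no gradient from that sum
alone; the trainer therefore adds the fused map's BCE as one more term by
default (`include_fused_loss = TRUE` in `train_config()`). Whether the
published four-term loss includes such a fused term cannot be determined
from its description; ours is configurable, and disabling it only stops the
small fusion head (S+1 weights) from adapting.

### Why a native implementation

No deep-learning framework is available to R in this toolchain, and the
network itself is the package's scientific core, so the forward/backward
passes are implemented directly: a small define-by-run tape in R over
compiled kernels (depthwise convolution, GEMM-based 1×1 convolution, batch
normalization, pooling, separable bilinear interpolation, SiLU). Every
kernel's analytic gradient is validated against central differences in the
test suite, including end-to-end through a whole model.

## The scene simulator

The simulator stands in for labeled Sentinel-1 GRD VV scenes, which are not
distributable here. A scene is a constant sea-clutter reflectivity with
groups of parallel rectangular rafts (each group shares one orientation,
raft size, and spacing), observed under fully developed multiplicative
speckle: each pixel is multiplied by an independent Gamma(ENL, ENL) variate
(mean 1, coefficient of variation `1/sqrt(ENL)`). Masks are exact by
construction — a pixel is raft iff its center lies inside a raft rectangle —
so the metric oracles are exact too.

Defaults are chosen once to be plausible for ~10 m pixels in calibrated VV
backscatter: sea σ⁰ `0.03` (≈ −15 dB), rafts 4× brighter (`0.12`), ENL 4,
raft length 24–64 px, width 4–9 px, gaps 3–7 px, 3–8 rafts per group. Raft
contrast polarity is configurable (dark rafts occur in some sea states); the
default is bright. The published work gives no quantitative description of
its scenes' backscatter statistics, so these are free parameters of the
artifact, not calibrated values.

What the simulator deliberately omits: wind-streak and wave textures
(clutter is stationary), radar geometry (layover, incidence-angle trends),
inter-scene radiometric drift, and label noise from manual digitization.
Passing tests on synthetic scenes therefore demonstrate that the
architecture, optimization and evaluation machinery are correct and that
the model can learn speckled rectangular structure — not that any accuracy
level transfers to real Sentinel-1 scenes.

## Refined Lee despeckling

Preprocessing applies the 7×7 Refined Lee filter. The filter's name alone
does not fix an algorithm, so the implementation follows the standard
directional-window formulation and documents it: a 3×3 template of 3×3
sub-block means (centers offset by ±2 for the 7×7 window) estimates the
dominant gradient direction among four orientations; one of eight
edge-aligned half-windows (28 of 49 pixels, center line included) is chosen
on the side whose mean is closer to the center block mean; minimum
mean-square-error weighting
`x̂ = m + k·(y − m)`, `k = clamp((var − m²·Cu²)/((1 + Cu²)·var), 0, 1)`
is applied with the half-window statistics, `Cu = 1/sqrt(ENL)`. Exact
numeric parity with any particular toolbox implementation (e.g. SNAP's) is
not a goal.

Numerical conventions: borders are symmetric-reflect padded so output shape
equals input shape; a zero-variance window forces `k = 0` (no division);
clamping `k` to `[0, 1]` makes each output a convex combination of the
half-window mean and the center pixel, hence bounded by the local window
extremes. When the ENL is unknown, `Cu²` is estimated as the minimum local
squared coefficient of variation over the image — the classical
homogeneous-area heuristic.

Near an ideal step edge the filter is compared against a plain 7×7 boxcar
within the six-column band the window straddles (the *edge* band): the
boxcar necessarily blurs the step there, the directional half-windows do
not. Away from edges a 49-pixel boxcar averages more samples than a
28-pixel half-window, so global variance comparisons favor the boxcar on
purely flat scenes; edge fidelity is what the refined filter buys.

## Dataset pipeline

* **Tiling**: row-major grid of `tile_size` blocks (0-based origins,
  half-open windows), partial edge blocks discarded. The reference pipeline
  cuts 685 blocks of 320×320.
* **Augmentation**: each source tile yields exactly six samples — identity,
  horizontal flip, vertical flip, 180° rotation, and both diagonal mirrors —
  with the mask transformed by the same operator. The named operator list
  ends in "etc." in the source description, but the stated counts
  (685 → 4110) force a factor of six, which the flip/mirror subgroup of the
  dihedral group supplies exactly (no ±90° rotations).
* **Split**: uniform 3:1:1 partition with largest-remainder rounding
  (685 → 411/137/137), seeded. The split is made *by source tile*, and all
  six augmented variants inherit the source's label, so augmentation and
  splitting commute and no augmented copy of a training tile can leak into
  validation or test. Whether the original pipeline split before or after
  augmentation is unstated; the leakage-safe order is the defensible one.
* **Normalization**: per-tile min–max to `[0, 1]` (constant tiles map to
  zero); the network consumes normalized linear intensity, with the dB view
  reserved for display.

## Training

`train_config()` defaults mirror the reference recipe: Adam, learning rate
`1e−5`, decay factor `1e−3`, 200 epochs, batch size 4. The "decay factor"
is interpreted as Adam weight decay (L2 added to the gradient), since no
schedule shape is described; `decay_mode = "lr"` alternatively applies it
as an inverse-time learning-rate schedule. Epoch shuffling uses a seeded
generator; training twice with one seed is bit-identical, and the weights
returned are those of the best-validation epoch. Non-finite loss aborts
with the offending epoch.

## Problem sizes used by the tests and acceptance script

All empirical checks run on simulated data at desk scale, sizes chosen as
this package's own test design:

* **Desk-scale learning**: one 512×960 scene (15 raft groups) cut into 120
  64-px tiles, split 3:1:1 (72/24/24); W-3 with `C0 = 8` (~25k parameters)
  trained 30 epochs, batch 4, learning rate `1e−3`, weight decay `1e−3`.
  The learning rate is raised from the reference `1e−5` because a 30-epoch
  desk run has no room for that schedule's slow convergence; the reference
  values remain the defaults. Held-out quality is pooled-pixel IoU on the
  test split against the exact masks, compared with the all-positive
  baseline.
* **Residual ablation**: five matched seeds; per seed one 256×256 scene,
  64 32-px tiles split 3:1:1, 12 epochs with and without residual
  connections from identical initializations; final validation losses are
  compared.
* **Metric oracle**: all 512×512 = 262,144 pairs of 3×3 binary masks against
  a per-pixel brute-force loop.
* **Speckle statistics**: 10⁴-pixel flat fields, 3-standard-error bands.

## Other numerical choices

* Bilinear 2× up-sampling uses half-pixel-center alignment with border
  clamping (the `align_corners = false` convention), fixed and documented
  for reproducibility; the backward pass is its exact adjoint.
* Batch normalization: ε `1e−5`, running-statistics momentum 0.1, biased
  batch variance for normalization and unbiased for the running estimate;
  evaluation mode uses running statistics.
* Sigmoid outputs are clamped to `[1e−12, 1 − 1e−12]` so probability maps
  honor the open-interval contract even where the logistic saturates in
  double precision; the BCE separately clamps at `1e−7`.
* Metrics: `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`,
  `IoU = tp/(tp+fp+fn)`. Zero-denominator conventions: all metrics 1 when
  both masks are empty; a zero denominator otherwise yields 0. F1 is the
  harmonic mean and so always lies between precision and recall — the suite
  asserts this, and it is why externally reported metric tables whose F1
  exceeds both P and R cannot be reproduced by these standard definitions.
* Stitched prediction averages probabilities in overlap regions (default
  overlap 0, i.e. disjoint blocks, matching block-wise prediction of large
  scenes) and binarizes at 0.5; scenes smaller than one tile are
  reflect-padded and cropped back.
* Max-pool ties resolve to the first maximum in column-major order; the
  gradient is routed to that pixel alone.

## Known limitations

* The simulator's stationary gamma speckle is the simplest credible SAR
  noise model; no spatial correlation of speckle, no multiplicative trends.
* Desk-scale results (small tiles, tiny channel widths, tens of epochs) are
  capacity- and budget-limited; they validate machinery and direction, not
  attainable accuracy at 320-px tiles and 200 epochs.
* The checkpoint format is R's native serialization; portability to other
  frameworks is out of scope.
* Published absolute metric values for the real Liaoning/Fujian scenes
  require the original labeled data, which is not deposited anywhere
  accessible, and GPU-scale training; they are outside what this artifact
  can or attempts to reproduce.
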