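# waveseg

Semantic segmentation of marine raft aquaculture in SAR imagery with the
wave-shaped **Wave-Net** architecture, plus everything needed to run and test
the pipeline end to end on a desk: a speckled-scene simulator with exact
ground truth, Refined Lee despeckling, tiling/augmentation/splitting, native
training (reverse-mode autodiff + Adam on compiled kernels), and a
metrics/stitching evaluation kit.

## Who this is for

Remote-sensing and coastal-monitoring researchers who map raft aquaculture
(longlines, rafts, cages — regular rectangular arrays) from single-band SAR
backscatter, and anyone who wants a fully self-contained, inspectable R
implementation of a nested encoder–decoder segmentation network with deep
supervision.

## The model

Wave-Net cascades a **feature aggregation** part — `L` asymmetric V-shaped
subnetworks (encode by 2×2 max-pooling, decode by bilinear 2× up-sampling,
identical-scale fusion) with 2×2 pooling between stages — and a **feature
dispersion** part — `L` asymmetric Λ-shaped subnetworks (up-sample first,
then reduce) with 2× up-sampling between stages. Every convolution is a
depthwise 3×3 + pointwise 1×1 unit with batch normalization and SiLU;
every subnetwork carries a residual connection. With the default depth
schedules each V bottoms at `H/2^L` and each Λ crests at `2H`, so feature
resolution traces a wave across the network.

Stage-wise aggregation/dispersion features at identical scale are fused and
passed through 1×1 + sigmoid heads, giving `S = L + 1` side probability maps
at input resolution (four at the reference depth `L = 3`); training
minimizes the multi-scale loss

    L_total = Σ_{s=1..S} BCE(side_s, truth)   (+ BCE(fused, truth))

and prediction thresholds the fused map. Tile size selects the depth:
`[300,400) → L=3`, `[400,500) → L=4`, `[500,600] → L=5`. Standard metrics
(`P`, `R`, `F1`, `IoU`) are computed from pooled pixel confusion counts.

The speckle simulator uses the fully developed multiplicative model:
linear-intensity reflectivity times independent Gamma(ENL, ENL) variates
(mean 1, CV = 1/√ENL). The despeckler is the classical 7×7 Refined Lee
filter (directional half-windows + MMSE weighting).

See `vignettes/waveseg-methods.Rmd` for the full model description, the
simulator's assumptions, and every numerical convention.

## Worked example

```r
library(waveseg)

# 1. simulate a speckled SAR scene with exact ground truth
scene <- simulate_scene(scene_params(height_px = 256, width_px = 256,
                                     n_raft_groups = 7, seed = 42))
print(scene)

# 2. despeckle (7x7 Refined Lee), then tile / split 3:1:1
filtered <- refined_lee(scene$intensity, lee_params(window = 7, enl = 4))
tiles <- split_tiles(tile_scene(filtered, scene$mask, tile_size = 64),
                     c(3, 1, 1), seed = 1)
print(tiles)

# 3. build and train a small Wave-Net (W-3)
model <- build_wavenet(wavenet_config(L = 3, base_channels = 8), seed = 1)
fit <- train_wavenet(model, tiles,
                     train_config(epochs = 40, batch_size = 4,
                                  learning_rate = 1e-3, seed = 1))

# 4. evaluate on the held-out test tiles
ev <- evaluate_tiles(fit$model, tiles, split = "test")
print(ev$metrics)
```

Output of this exact script (a few minutes on one CPU):

```
sar_scene: 256 x 256 px, 7 raft group(s) requested, ENL 4
  raft fraction 0.159; intensity range [0.001158, 0.4438] (linear)
wn_tileset: 16 tile(s) of 64 x 64; splits train/val/test = 10/3/3
wn_train_history: 40 epoch(s), best epoch 40
  final train 0.5018, final val 1.1492
metrics_report: precision 0.8922, recall 0.6037, f1 0.7201, iou 0.5627
```

Reading the numbers: the simulated scene is 15.9% raft pixels; training on
ten 64-px tiles for 40 epochs brings the summed multi-scale BCE down to
0.50 on the training split, and the held-out test tiles score IoU 0.56 — a
toy-sized run. At the package's desk-scale reference configuration (120 tiles, 30
epochs; see the acceptance script) the same model reaches held-out IoU
above 0.7 against an all-positive baseline near 0.05. Larger tiles, wider
channels and the default 200-epoch schedule are the intended real-data
regime.

A command-line front end over the same functions lives in
`inst/cli/waveseg.R`:

```sh
Rscript inst/cli/waveseg.R simulate --seed 1 --out scene/
Rscript inst/cli/waveseg.R despeckle --window 7 --enl 4 scene/intensity.tif filtered.tif
Rscript inst/cli/waveseg.R dataset --tile-size 64 --seed 1 scene/intensity.tif scene/mask.tif tiles/
Rscript inst/cli/waveseg.R train --data tiles/ --out run/
Rscript inst/cli/waveseg.R predict --model run/model.rds --image scene/intensity.tif --tile-size 64 --out mask.tif
Rscript inst/cli/waveseg.R eval --pred mask.tif --truth scene/mask.tif --out report.json
```

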