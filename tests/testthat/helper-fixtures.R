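# Shared fixtures and oracles for the test suite. Everything is generated in
# code at test time; nothing is read from disk.

# access to internals under test (autodiff ops, subnet constructors)
wn <- asNamespace("waveseg")

# central-difference gradient check of a scalar-valued tape computation.
# `fwd()` must rebuild the graph from the current tensor values and return
# the scalar loss tensor; `tensors` is a named list of wn_tensor nodes.
expect_gradcheck <- function(fwd, tensors, n_probe = 5, h = 1e-6, tol = 1e-4) {
  lt <- fwd()
  wn$backward(lt)
  grads <- lapply(tensors, function(tt) tt$grad)
  for (nm in names(tensors)) {
    tt <- tensors[[nm]]
    idx <- sample(length(tt$value), min(n_probe, length(tt$value)))
    for (i in idx) {
      v0 <- tt$value[i]
      tt$value[i] <- v0 + h
      lp <- fwd()$value
      tt$value[i] <- v0 - h
      lm <- fwd()$value
      tt$value[i] <- v0
      num <- (lp - lm) / (2 * h)
      expect_lt(abs(num - grads[[nm]][i]), tol * max(1, abs(num)),
                label = sprintf("gradient of %s[%d] (analytic %.6g vs numeric %.6g)",
                                nm, i, grads[[nm]][i], num))
    }
    tt$grad <- NULL
  }
  invisible(TRUE)
}

# brute-force per-pixel confusion oracle: explicit loop over pixels
oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] > 0
    t <- truth[i] > 0
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# metrics from oracle counts, same conventions, written independently
oracle_metrics <- function(cf) {
  if (cf$tp + cf$fp + cf$fn == 0L) return(list(precision = 1, recall = 1, f1 = 1, iou = 1))
  p <- if (cf$tp + cf$fp > 0) cf$tp / (cf$tp + cf$fp) else 0
  r <- if (cf$tp + cf$fn > 0) cf$tp / (cf$tp + cf$fn) else 0
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
       iou = cf$tp / (cf$tp + cf$fp + cf$fn))
}

# a small speckled scene fixture
tiny_scene <- function(seed = 7L, h = 128L, w = 128L, groups = 3L) {
  simulate_scene(scene_params(height_px = h, width_px = w,
                              n_raft_groups = groups, seed = seed))
}

# a split tileset of 32x32 tiles from one simulated scene
tiny_tileset <- function(seed = 7L, h = 128L, w = 192L, tile = 32L, groups = 5L) {
  sc <- simulate_scene(scene_params(height_px = h, width_px = w,
                                    n_raft_groups = groups, seed = seed))
  split_tiles(tile_scene(sc$intensity, sc$mask, tile), c(3, 1, 1),
              seed = seed + 1L)
}

# every 3x3 binary mask, one per row
all_3x3_masks <- function() {
  t(sapply(0:511, function(k) as.integer(intToBits(k)[1:9])))
}
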