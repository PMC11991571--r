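# Pixel-level segmentation metrics, multi-run aggregation, and block-wise
# prediction of scenes larger than one tile.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary matrices/arrays of identical shape (values in
#'   \{0,1\}; anything > 0 counts as foreground).
#' @return a `wn_confusion` with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim_as4(pred) == dim_as4(truth)))
    stop("pred and truth shapes differ")
  p <- pred > 0
  t <- truth > 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "wn_confusion")
}

#' @export
print.wn_confusion <- function(x, ...) {
  cat(sprintf("wn_confusion: tp %d, fp %d, fn %d, tn %d (%d px)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

# add two confusion objects (pooling pixels)
add_confusion <- function(a, b) {
  structure(list(tp = a$tp + b$tp, fp = a$fp + b$fp,
                 fn = a$fn + b$fn, tn = a$tn + b$tn), class = "wn_confusion")
}

#' Precision, recall, F1 and IoU from confusion counts
#'
#' Standard definitions: `P = tp/(tp+fp)`, `R = tp/(tp+fn)`,
#' `F1 = 2PR/(P+R)` (the harmonic mean, so F1 always lies between P and R),
#' `IoU = tp/(tp+fp+fn)`. Zero-denominator conventions: when both masks are
#' empty all four metrics are 1; otherwise an empty denominator gives 0.
#'
#' @param x a `wn_confusion` from [confusion_counts()], or a prediction mask
#'   (with `truth` supplied).
#' @param truth optional truth mask when `x` is a prediction.
#' @return a `metrics_report` with fields `precision`, `recall`, `f1`, `iou`
#'   and `n_runs = 1`.
#' @export
seg_metrics <- function(x, truth = NULL) {
  if (!inherits(x, "wn_confusion")) x <- confusion_counts(x, truth)
  tp <- x$tp; fp <- x$fp; fn <- x$fn
  if (tp + fp + fn == 0) {
    p <- r <- f1 <- iou <- 1
  } else {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    iou <- tp / (tp + fp + fn)
  }
  structure(list(precision = p, recall = r, f1 = f1, iou = iou, n_runs = 1L),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  if (x$n_runs > 1L) {
    cat(sprintf("metrics_report over %d runs (mean +/- sd):\n", x$n_runs))
    for (m in c("precision", "recall", "f1", "iou"))
      cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  } else {
    cat(sprintf("metrics_report: precision %.4f, recall %.4f, f1 %.4f, iou %.4f\n",
                x$precision, x$recall, x$f1, x$iou))
  }
  invisible(x)
}

#' Aggregate metric reports over repeated runs
#'
#' Per-metric sample mean and sample standard deviation (n - 1 denominator)
#' over independent repeats, the way repeated-run tables are reported.
#'
#' @param reports list of >= 2 `metrics_report` objects.
#' @return a `metrics_report` with `mean` and `sd` lists and
#'   `n_runs = length(reports)`; the top-level metric fields hold the means.
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 2,
            all(vapply(reports, inherits, TRUE, "metrics_report")))
  ms <- c("precision", "recall", "f1", "iou")
  vals <- sapply(ms, function(m) vapply(reports, `[[`, numeric(1), m))
  mean_l <- as.list(colMeans(vals))
  sd_l <- as.list(apply(vals, 2, stats::sd))
  structure(c(mean_l, list(n_runs = length(reports), mean = mean_l, sd = sd_l)),
            class = "metrics_report")
}

# build a tile -> probability-map predictor from a model or a function
as_predictor <- function(model) {
  if (is.function(model)) return(model)
  stopifnot(inherits(model, "wavenet_model"))
  function(tile) wn_forward(model, normalize_tile(tile))$fused_map
}

#' Block-wise prediction of a large scene
#'
#' Cuts the scene into `tile_size` blocks (step `tile_size - overlap`, with a
#' final offset block flush against each edge so every pixel is covered),
#' predicts each block independently, averages probabilities where blocks
#' overlap, and thresholds. A scene smaller than one tile is reflect-padded
#' to tile size and the prediction cropped back.
#'
#' @param model a `wavenet_model` (tiles are min-max normalized before the
#'   forward pass and the fused map is used), or any
#'   `function(tile_matrix) -> probability matrix` for harness use.
#' @param scene_image numeric matrix (raw intensity).
#' @param tile_size block side length; must be divisible by `2^L` for a
#'   Wave-Net model.
#' @param overlap overlap in pixels between neighboring blocks (default 0,
#'   disjoint blocks).
#' @param threshold binarization threshold on the averaged probabilities.
#' @return binary integer matrix of the scene's shape.
#' @export
stitch_predict <- function(model, scene_image, tile_size, overlap = 0,
                           threshold = 0.5) {
  stopifnot(is.matrix(scene_image), tile_size >= 1,
            overlap >= 0, overlap < tile_size)
  predict_fn <- as_predictor(model)
  H <- nrow(scene_image); W <- ncol(scene_image)
  padH <- max(tile_size - H, 0L); padW <- max(tile_size - W, 0L)
  img <- reflect_pad(scene_image, padH, padW)
  h <- nrow(img); w <- ncol(img)
  stride <- tile_size - overlap
  rstarts <- unique(c(seq(0L, h - tile_size, by = stride), h - tile_size))
  cstarts <- unique(c(seq(0L, w - tile_size, by = stride), w - tile_size))
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (r in rstarts) for (cl in cstarts) {
    ri <- r + seq_len(tile_size); ci <- cl + seq_len(tile_size)
    p <- predict_fn(img[ri, ci])
    stopifnot(all(dim(p) == c(tile_size, tile_size)))
    acc[ri, ci] <- acc[ri, ci] + p
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  prob <- acc / cnt
  out <- matrix(as.integer(prob >= threshold), h, w)
  out[seq_len(H), seq_len(W), drop = FALSE]
}

reflect_pad <- function(x, padH, padW) {
  if (padH > 0) {
    ref <- x[rev(seq_len(min(padH, nrow(x)))), , drop = FALSE]
    while (nrow(ref) < padH) ref <- rbind(ref, ref)
    x <- rbind(x, ref[seq_len(padH), , drop = FALSE])
  }
  if (padW > 0) {
    ref <- x[, rev(seq_len(min(padW, ncol(x)))), drop = FALSE]
    while (ncol(ref) < padW) ref <- cbind(ref, ref)
    x <- cbind(x, ref[, seq_len(padW), drop = FALSE])
  }
  x
}

#' Evaluate a model on one split of a tile set
#'
#' Predicts every tile of the chosen split (fused map, threshold 0.5 by
#' default), pools the pixel confusion over tiles, and reports the standard
#' metrics.
#'
#' @param model a `wavenet_model` or predictor function.
#' @param tileset a split `wn_tileset`.
#' @param split which split to evaluate (default `"test"`).
#' @param threshold binarization threshold.
#' @param chunk forward-pass batch size.
#' @return list with `metrics` (a `metrics_report`) and `confusion`.
#' @export
evaluate_tiles <- function(model, tileset, split = "test", threshold = 0.5,
                           chunk = 8L) {
  tiles <- split_subset(tileset, split)
  stopifnot(length(tiles) > 0)
  conf <- structure(list(tp = 0, fp = 0, fn = 0, tn = 0), class = "wn_confusion")
  if (is.function(model)) {
    for (t in tiles) {
      pred <- model(t$image) >= threshold
      conf <- add_confusion(conf, confusion_counts(pred, t$mask))
    }
  } else {
    b <- tiles_to_batch(tiles)
    n <- dim(b$x)[4]
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      out <- wn_forward(model, b$x[, , , idx, drop = FALSE])
      pred <- out$fused_map >= threshold
      truth <- array(b$y[, , 1, idx], dim = c(dim(b$y)[1:2], length(idx)))
      conf <- add_confusion(conf, confusion_counts(pred, truth))
    }
  }
  list(metrics = seg_metrics(conf), confusion = conf)
}
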