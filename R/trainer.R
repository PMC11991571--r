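# Training loop: multi-scale BCE loss fusion + Adam.

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with
#' (learning rate, decay factor) = (1e-5, 1e-3), 200 epochs, batch size 4.
#' The decay factor is applied as Adam weight decay by default;
#' `decay_mode = "lr"` instead uses it as an inverse-time learning-rate
#' schedule `lr / (1 + decay * (epoch - 1))`.
#'
#' @param epochs number of passes over the training split (>= 0).
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param weight_decay the decay factor.
#' @param decay_mode `"weight"` (L2 into the gradient) or `"lr"` (schedule).
#' @param optimizer only `"adam"` is implemented.
#' @param seed integer seed for shuffling (training is fully reproducible).
#' @param include_fused_loss add the fused map's BCE to the side-output sum
#'   so the fusion head is trained (default `TRUE`).
#' @param checkpoint_every write a checkpoint every this many epochs into
#'   `checkpoint_dir` (0 = never).
#' @param checkpoint_dir directory for periodic checkpoints.
#' @param device opaque identifier, kept for config compatibility.
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 200L, batch_size = 4L,
                         learning_rate = 1e-5, weight_decay = 1e-3,
                         decay_mode = c("weight", "lr"),
                         optimizer = "adam", seed = 1L,
                         include_fused_loss = TRUE,
                         checkpoint_every = 0L, checkpoint_dir = NULL,
                         device = "cpu") {
  decay_mode <- match.arg(decay_mode)
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, weight_decay >= 0)
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 decay_mode = decay_mode, optimizer = optimizer,
                 seed = as.integer(seed),
                 include_fused_loss = isTRUE(include_fused_loss),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir, device = device),
            class = "train_config")
}

#' Read a training config from YAML
#' @param path YAML file with `train_config` keys.
#' @return a `train_config`.
#' @export
train_config_from_yaml <- function(path) do.call(train_config, yaml::read_yaml(path))

#' Multi-scale binary cross-entropy loss
#'
#' Sum over the `S` side maps of the pixel-mean BCE
#' `-(t log p + (1 - t) log(1 - p))` against the binary target, with
#' probabilities clamped to `[eps, 1 - eps]`. With `include_fused = TRUE` the
#' fused map contributes one further term (the trainer's default, so the
#' fusion head receives gradient).
#'
#' @param output a `wn_segoutput` (arrays, from [wn_forward()]).
#' @param target binary mask: matrix, `(H, W, N)` or `(H, W, 1, N)` array.
#' @param include_fused include the fused map's BCE term.
#' @param eps clamping constant for the logarithms.
#' @return non-negative scalar loss.
#' @export
multiscale_bce <- function(output, target, include_fused = FALSE, eps = 1e-7) {
  stopifnot(inherits(output, "wn_segoutput"))
  maps <- output$side_maps
  if (include_fused) maps <- c(maps, list(output$fused_map))
  if (!all(target %in% c(0, 1))) stop("target must be binary")
  d <- dim(target)
  if (length(d) == 4L && d[3] == 1L)    # (H, W, 1, N) -> (H, W, N)
    target <- array(target, d[c(1, 2, 4)])
  sum(vapply(maps, function(p) {
    if (!all(dim_as4(p) == dim_as4(target)))
      stop("target shape does not match the side maps")
    bce_mean_num(p, target, eps)
  }, numeric(1)))
}

dim_as4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  c(d, rep(1L, 4 - length(d)))
}

bce_mean_num <- function(p, t, eps = 1e-7) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(pc) + (1 - t) * log(1 - pc))
}

# tensor-graph version used inside the training loop
multiscale_bce_t <- function(out_t, target, include_fused = TRUE, eps = 1e-7) {
  terms <- lapply(out_t$side, op_bce_mean, target = target, eps = eps)
  if (include_fused)
    terms <- c(terms, list(op_bce_mean(out_t$fused, target, eps = eps)))
  op_sum_scalars(terms)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(params, st, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  st
}

# ---- training loop ---------------------------------------------------------

#' Train a Wave-Net model
#'
#' Runs `config$epochs` epochs of minibatch Adam on the training split of
#' `tileset`, shuffling with a seeded generator each epoch, recording the
#' mean training and validation loss per epoch, and returning the weights of
#' the best-validation epoch. Fully reproducible from `config$seed`.
#'
#' @param model a `wavenet_model` (modified in place and returned).
#' @param tileset a split `wn_tileset` with non-empty train and val splits.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best-validation weights) and `history`
#'   (a `wn_train_history`: data frame of epoch, train_loss, val_loss, plus
#'   `best_epoch`).
#' @export
train_wavenet <- function(model, tileset, config = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "wavenet_model"), inherits(config, "train_config"))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  if (config$epochs == 0L)
    return(list(model = model,
                history = structure(history, best_epoch = NA_integer_,
                                    class = c("wn_train_history", "data.frame"))))
  tr <- split_subset(tileset, "train")
  va <- split_subset(tileset, "val")
  if (length(tr) == 0L || length(va) == 0L)
    stop("tileset needs non-empty train and val splits")
  btr <- tiles_to_batch(tr)
  bva <- tiles_to_batch(va)
  params <- collect_params(model)
  opt <- adam_init(params)
  wd_opt <- if (config$decay_mode == "weight") config$weight_decay else 0
  best <- Inf
  best_epoch <- NA_integer_
  best_state <- NULL
  n_tr <- dim(btr$x)[4]
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr_e <- if (config$decay_mode == "lr")
        config$learning_rate / (1 + config$weight_decay * (epoch - 1))
      else config$learning_rate
      ord <- sample.int(n_tr)
      loss_sum <- 0
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        xb <- new_tensor(btr$x[, , , idx, drop = FALSE])
        yb <- btr$y[, , , idx, drop = FALSE]
        zero_grads(params)
        out <- forward_wavenet_t(model, xb, training = TRUE)
        lt <- multiscale_bce_t(out, yb, include_fused = config$include_fused_loss)
        if (!is.finite(lt$value))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        backward(lt)
        opt <- adam_step(params, opt, lr_e, wd_opt)
        loss_sum <- loss_sum + lt$value * length(idx)
      }
      train_loss <- loss_sum / n_tr
      val_loss <- eval_loss(model, bva, config)
      history[epoch, ] <- list(epoch, train_loss, val_loss)
      if (verbose)
        cat(sprintf("epoch %3d  train %.4f  val %.4f\n", epoch, train_loss, val_loss))
      if (val_loss < best) {
        best <- val_loss
        best_epoch <- epoch
        best_state <- model_state(model)
      }
      if (config$checkpoint_every > 0L && epoch %% config$checkpoint_every == 0L &&
          !is.null(config$checkpoint_dir)) {
        dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        save_wavenet(model, file.path(config$checkpoint_dir,
                                      sprintf("epoch_%04d.rds", epoch)))
      }
    }
  })
  restore_state(model, best_state)
  list(model = model,
       history = structure(history, best_epoch = best_epoch,
                           class = c("wn_train_history", "data.frame")))
}

# mean validation loss in evaluation mode (running BN statistics, no grad)
eval_loss <- function(model, batch, config, chunk = 8L) {
  n <- dim(batch$x)[4]
  total <- 0
  with_no_grad({
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      xb <- new_tensor(batch$x[, , , idx, drop = FALSE])
      out <- forward_wavenet_t(model, xb, training = FALSE)
      lt <- multiscale_bce_t(out, batch$y[, , , idx, drop = FALSE],
                             include_fused = config$include_fused_loss)
      total <- total + lt$value * length(idx)
    }
  })
  total / n
}

#' @export
print.wn_train_history <- function(x, ...) {
  cat(sprintf("wn_train_history: %d epoch(s), best epoch %s\n",
              nrow(x), format(attr(x, "best_epoch"))))
  if (nrow(x) > 0)
    cat(sprintf("  final train %.4f, final val %.4f\n",
                x$train_loss[nrow(x)], x$val_loss[nrow(x)]))
  invisible(x)
}

#' Write a per-epoch CSV log from a training history
#' @param history a `wn_train_history`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}

#' Set the residual-connection flag of an architecture config
#'
#' Used by the ablation harness: `ablate_residuals(cfg)` returns the same
#' architecture with residual connections removed; pass `enabled = TRUE` to
#' restore them.
#'
#' @param config a `wavenet_config`.
#' @param enabled new value of `residuals_enabled` (default `FALSE`).
#' @return the modified config.
#' @export
ablate_residuals <- function(config, enabled = FALSE) {
  stopifnot(inherits(config, "wavenet_config"))
  config$residuals_enabled <- isTRUE(enabled)
  config
}
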