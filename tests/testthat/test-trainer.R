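# Multi-scale BCE loss arithmetic, Adam behavior, reproducible training.

make_segoutput <- function(maps, fused = maps[[1]]) {
  structure(list(side_maps = maps, fused_map = fused), class = "wn_segoutput")
}

test_that("multi-scale BCE matches closed-form arithmetic", {
  # four p = 0.5 maps against t = 1 on a single pixel: 4 * ln 2
  maps <- rep(list(matrix(0.5, 1, 1)), 4)
  out <- make_segoutput(maps)
  expect_equal(multiscale_bce(out, matrix(1, 1, 1)), 4 * log(2), tolerance = 1e-12)
  # perfect prediction: only the clamping epsilon remains
  perfect <- make_segoutput(rep(list(matrix(1, 4, 4)), 4))
  expect_lt(multiscale_bce(perfect, matrix(1, 4, 4)), 1e-5)
  # S identical maps = S times the single-map BCE
  set.seed(1)
  p <- matrix(runif(16, 0.1, 0.9), 4, 4)
  t <- matrix(rbinom(16, 1, 0.5), 4, 4)
  one <- multiscale_bce(make_segoutput(list(p)), t)
  five <- multiscale_bce(make_segoutput(rep(list(p), 5)), t)
  expect_equal(five, 5 * one)
  # the fused term is added on request
  expect_equal(multiscale_bce(make_segoutput(list(p), fused = p), t,
                              include_fused = TRUE), 2 * one)
})

test_that("loss validates shapes and targets", {
  out <- make_segoutput(list(matrix(0.5, 2, 2)))
  expect_error(multiscale_bce(out, matrix(1, 3, 3)), "shape")
  expect_error(multiscale_bce(out, matrix(0.5, 2, 2)), "binary")
})

test_that("one Adam step with zero learning rate changes nothing", {
  model <- build_wavenet(wavenet_config(L = 3, base_channels = 4), seed = 3)
  params <- wn$collect_params(model)
  before <- lapply(params, function(p) p$value)
  xt <- wn$new_tensor(array(runif(16 * 16), c(16, 16, 1, 1)))
  tgt <- array(rbinom(16 * 16, 1, 0.3), c(16, 16, 1, 1))
  wn$zero_grads(params)
  lt <- wn$multiscale_bce_t(wn$forward_wavenet_t(model, xt, training = TRUE), tgt)
  wn$backward(lt)
  st <- wn$adam_init(params)
  wn$adam_step(params, st, lr = 0, weight_decay = 1e-3)
  expect_identical(lapply(params, function(p) p$value), before)
})

test_that("zero epochs return the model unchanged with empty history", {
  ts <- tiny_tileset(seed = 31)
  model <- build_wavenet(wavenet_config(L = 3, base_channels = 2), seed = 4)
  before <- lapply(wn$collect_params(model), function(p) p$value)
  fit <- train_wavenet(model, ts, train_config(epochs = 0, seed = 1))
  expect_identical(lapply(wn$collect_params(fit$model), function(p) p$value),
                   before)
  expect_equal(nrow(fit$history), 0)
})

test_that("a toy run learns and is bit-reproducible under a fixed seed", {
  ts <- tiny_tileset(seed = 32)
  cfg <- wavenet_config(L = 3, base_channels = 4)
  tc <- train_config(epochs = 5, batch_size = 4, learning_rate = 1e-3,
                     weight_decay = 1e-3, seed = 99)
  fit1 <- train_wavenet(build_wavenet(cfg, seed = 5), ts, tc)
  expect_equal(nrow(fit1$history), 5)
  expect_lt(fit1$history$train_loss[5], fit1$history$train_loss[1])
  expect_true(all(is.finite(fit1$history$val_loss)))
  expect_true(attr(fit1$history, "best_epoch") %in% 1:5)
  fit2 <- train_wavenet(build_wavenet(cfg, seed = 5), ts, tc)
  expect_identical(as.data.frame(fit1$history), as.data.frame(fit2$history))
})

test_that("the best-validation weights are the ones returned", {
  ts <- tiny_tileset(seed = 33)
  tc <- train_config(epochs = 4, batch_size = 4, learning_rate = 1e-3, seed = 7)
  fit <- train_wavenet(build_wavenet(wavenet_config(L = 3, base_channels = 4),
                                     seed = 6), ts, tc)
  best <- attr(fit$history, "best_epoch")
  expect_equal(fit$history$val_loss[best], min(fit$history$val_loss))
  # the returned model reproduces the best epoch's validation loss
  bva <- wn$tiles_to_batch(wn$split_subset(ts, "val"))
  re_val <- wn$eval_loss(fit$model, bva, tc)
  expect_equal(re_val, min(fit$history$val_loss), tolerance = 1e-10)
})

test_that("residual ablation is a pure config transform", {
  cfg <- wavenet_config(L = 3)
  off <- ablate_residuals(cfg)
  expect_false(off$residuals_enabled)
  expect_true(ablate_residuals(off, enabled = TRUE)$residuals_enabled)
  # double application with negated flags restores the original
  expect_identical(cfg, ablate_residuals(ablate_residuals(cfg), enabled = TRUE))
  # everything but the flag is untouched
  expect_identical(off[setdiff(names(off), "residuals_enabled")],
                   cfg[setdiff(names(cfg), "residuals_enabled")])
})

test_that("an ablated model trains without error", {
  ts <- tiny_tileset(seed = 34)
  cfg <- ablate_residuals(wavenet_config(L = 3, base_channels = 4))
  fit <- train_wavenet(build_wavenet(cfg, seed = 8), ts,
                       train_config(epochs = 2, learning_rate = 1e-3, seed = 2))
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("the decay factor can act as an inverse-time learning-rate schedule", {
  ts <- tiny_tileset(seed = 35)
  tc <- train_config(epochs = 2, learning_rate = 1e-3, weight_decay = 0.5,
                     decay_mode = "lr", seed = 3)
  fit <- train_wavenet(build_wavenet(wavenet_config(L = 3, base_channels = 2),
                                     seed = 9), ts, tc)
  expect_equal(nrow(fit$history), 2)
})

test_that("a single tile can be overfit to near-zero loss", {
  # capacity / plumbing sanity: drive W-3 onto one synthetic tile
  sc <- tiny_scene(seed = 36, h = 32, w = 32, groups = 2)
  x <- wn$new_tensor(array(normalize_tile(sc$intensity), c(32, 32, 1, 1)))
  tgt <- array(sc$mask, c(32, 32, 1, 1))
  model <- build_wavenet(wavenet_config(L = 3, base_channels = 8), seed = 10)
  params <- wn$collect_params(model)
  st <- wn$adam_init(params)
  loss <- Inf
  for (k in 1:120) {
    wn$zero_grads(params)
    lt <- wn$multiscale_bce_t(wn$forward_wavenet_t(model, x, training = TRUE),
                              tgt, include_fused = TRUE)
    wn$backward(lt)
    st <- wn$adam_step(params, st, 3e-3)
    loss <- lt$value
  }
  # mean per-map pixel loss below 0.05
  expect_lt(loss / 5, 0.05)
})

test_that("training histories export to CSV", {
  h <- structure(data.frame(epoch = 1:2, train_loss = c(1, 0.5),
                            val_loss = c(1.1, 0.6)),
                 best_epoch = 2L, class = c("wn_train_history", "data.frame"))
  f <- tempfile(fileext = ".csv")
  write_history_csv(h, f)
  back <- read.csv(f)
  expect_equal(back$val_loss, c(1.1, 0.6))
  unlink(f)
})
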