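# Wave-Net architecture: configuration invariants, shape closure, residual
# behavior, parameter counting and gradient flow.

test_that("configuration invariants are enforced", {
  cfg <- wavenet_config(L = 3)
  expect_identical(cfg$side_outputs, 4L)              # four side outputs at L = 3
  expect_identical(cfg$v_heights, c(4L, 3L, 2L))
  expect_identical(cfg$lambda_heights, c(2L, 3L, 4L)) # mirror, deepest-first
  expect_identical(cfg$channel_schedule, c(32L, 64L, 128L))
  expect_identical(wavenet_config(L = 5, base_channels = 8)$channel_schedule,
                   c(8L, 16L, 32L, 64L, 64L))         # capped at 8 * C0
  expect_error(wavenet_config(L = 2), "L must be")
  expect_error(wavenet_config(L = 3, v_heights = c(3, 3, 2)), "decreasing")
  expect_error(wavenet_config(L = 3, v_heights = c(4, 3, 1)), "decreasing")
  expect_error(wavenet_config(L = 3, lambda_heights = c(2, 3)), "length L")
})

test_that("side maps close over the input shape with S = L + 1", {
  for (L in 3:5) {
    cfg <- wavenet_config(L = L, base_channels = 4)
    model <- build_wavenet(cfg, seed = 1)
    for (sz in c(2^L, 2^L * 2)) {
      out <- wn_forward(model, matrix(runif(sz * sz), sz, sz))
      expect_length(out$side_maps, L + 1)
      for (p in out$side_maps) expect_equal(dim(p), c(sz, sz))
      expect_equal(dim(out$fused_map), c(sz, sz))
      vals <- c(unlist(out$side_maps), out$fused_map)
      expect_true(all(vals > 0 & vals < 1))           # strict sigmoid range
    }
  }
})

test_that("batched input keeps per-sample shapes", {
  model <- build_wavenet(wavenet_config(L = 3, base_channels = 4), seed = 2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  out <- wn_forward(model, x)
  expect_equal(dim(out$fused_map), c(32, 32, 3))
  expect_length(out$side_maps, 4)
})

test_that("invalid input sizes name the smallest valid padded size", {
  model <- build_wavenet(wavenet_config(L = 3, base_channels = 4), seed = 1)
  expect_error(wn_forward(model, matrix(0.5, 20, 20)), "24x24")
  model5 <- build_wavenet(wavenet_config(L = 5, base_channels = 2), seed = 1)
  expect_error(wn_forward(model5, matrix(0.5, 40, 40)), "64x64")
})

test_that("V and Lambda subnets preserve spatial shape and support residuals", {
  set.seed(3)
  x <- wn$new_tensor(array(rnorm(32 * 32 * 4 * 2), c(32, 32, 4, 2)))
  for (h in 2:4) {
    v <- wn$new_v_subnet(h, 4, 6, 4, residual = TRUE)
    y <- wn$with_no_grad(wn$fwd_v_subnet(v, x, training = FALSE))
    expect_equal(dim(y$value), c(32, 32, 4, 2))
    l <- wn$new_lambda_subnet(h, 4, 6, 4, residual = TRUE)
    z <- wn$with_no_grad(wn$fwd_lambda_subnet(l, x, training = FALSE))
    expect_equal(dim(z$value), c(32, 32, 4, 2))
  }
})

test_that("zeroed convolutions with residual on reduce to the identity map", {
  set.seed(4)
  v <- wn$new_v_subnet(3, 4, 8, 4, residual = TRUE)   # cin == cout: pure identity
  for (p in wn$collect_params(v)) p$value <- p$value * 0
  x <- wn$new_tensor(array(rnorm(16 * 16 * 4), c(16, 16, 4, 1)))
  y <- wn$with_no_grad(wn$fwd_v_subnet(v, x, training = FALSE))
  expect_equal(y$value, x$value)
  # residual off: zeroed block maps to zero
  v0 <- wn$new_v_subnet(3, 4, 8, 4, residual = FALSE)
  for (p in wn$collect_params(v0)) p$value <- p$value * 0
  y0 <- wn$with_no_grad(wn$fwd_v_subnet(v0, x, training = FALSE))
  expect_true(all(y0$value == 0))
})

test_that("disabling residuals changes only identity paths, shapes unchanged", {
  cfg_on <- wavenet_config(L = 3, base_channels = 4)
  cfg_off <- ablate_residuals(cfg_on)
  expect_false(cfg_off$residuals_enabled)
  m_on <- build_wavenet(cfg_on, seed = 5)
  m_off <- build_wavenet(cfg_off, seed = 5)
  x <- matrix(runif(32 * 32), 32, 32)
  o_on <- wn_forward(m_on, x)
  o_off <- wn_forward(m_off, x)
  expect_equal(dim(o_on$fused_map), dim(o_off$fused_map))
  expect_length(o_off$side_maps, 4)
  # the identity-only residual paths carry no weights of their own
  expect_gte(count_parameters(m_on), count_parameters(m_off))
})

test_that("parameter count follows the documented formula and is monotone", {
  # one DWC unit, 8 -> 16 channels: depthwise 8*9+8, pointwise 8*16+16, BN 2*16
  cu <- wn$new_conv_unit(8, 16)
  expect_identical(count_parameters(cu), 80 + 144 + 32)
  c3 <- count_parameters(build_wavenet(wavenet_config(L = 3, base_channels = 16), seed = 1))
  c4 <- count_parameters(build_wavenet(wavenet_config(L = 4, base_channels = 16), seed = 1))
  expect_lt(c3, c4)
  counts <- sapply(c(8, 16, 32), function(c0)
    count_parameters(build_wavenet(wavenet_config(L = 3, base_channels = c0), seed = 1)))
  expect_true(all(diff(counts) > 0))
})

test_that("initialization is reproducible from the seed", {
  m1 <- build_wavenet(wavenet_config(L = 3, base_channels = 4), seed = 11)
  m2 <- build_wavenet(wavenet_config(L = 3, base_channels = 4), seed = 11)
  p1 <- wn$collect_params(m1); p2 <- wn$collect_params(m2)
  expect_identical(lapply(p1, function(p) p$value), lapply(p2, function(p) p$value))
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(wn_forward(m1, x), wn_forward(m2, x))
})

test_that("every parameter receives a finite gradient after one step", {
  set.seed(6)
  model <- build_wavenet(wavenet_config(L = 3, base_channels = 4), seed = 7)
  params <- wn$collect_params(model)
  xt <- wn$new_tensor(array(runif(32 * 32), c(32, 32, 1, 1)))
  tgt <- array(rbinom(32 * 32, 1, 0.3), c(32, 32, 1, 1))
  wn$zero_grads(params)
  lt <- wn$multiscale_bce_t(wn$forward_wavenet_t(model, xt, training = TRUE),
                            tgt, include_fused = TRUE)
  wn$backward(lt)
  for (p in params) {
    expect_false(is.null(p$grad))
    expect_true(all(is.finite(p$grad)))
  }
  st <- wn$adam_init(params)
  st <- wn$adam_step(params, st, 1e-3)
  expect_true(all(vapply(params, function(p) all(is.finite(p$value)), TRUE)))
})

test_that("checkpoints round-trip through save and load", {
  model <- build_wavenet(wavenet_config(L = 3, base_channels = 4), seed = 8)
  x <- matrix(runif(32 * 32), 32, 32)
  f <- tempfile(fileext = ".rds")
  save_wavenet(model, f)
  model2 <- load_wavenet(f)
  expect_identical(wn_forward(model, x), wn_forward(model2, x))
  unlink(f)
})

test_that("YAML configs build valid models", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("L: 4", "base_channels: 4", "residuals_enabled: false"), f)
  cfg <- wavenet_config_from_yaml(f)
  expect_identical(cfg$L, 4L)
  expect_false(cfg$residuals_enabled)
  expect_identical(cfg$side_outputs, 5L)
  unlink(f)
})
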