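# The Wave-Net architecture: a cascade of asymmetric V-shaped feature
# aggregation subnetworks followed by asymmetric Lambda-shaped feature
# dispersion subnetworks, with residual connections inside every subnetwork,
# identical-scale fusion between the two parts, and one sigmoid side output
# per fused scale plus a final full-resolution head. With the default depth
# schedules every V subnetwork bottoms out at H / 2^L and every Lambda
# subnetwork crests at 2 H, tracing the wave the model is named after.

#' Wave-Net architecture configuration
#'
#' @param L number of V-shaped (and Lambda-shaped) subnetworks, in \{3,4,5\};
#'   chosen from the tile size by [select_architecture()].
#' @param base_channels stage-1 channel count C0 (default 32).
#' @param channel_schedule per-stage channel counts; default
#'   `min(C0 * 2^(i-1), 8 * C0)`.
#' @param v_heights internal depth of each V subnetwork, strictly decreasing;
#'   default `L+1, L, ..., 2` so each V pools down to `H / 2^L`.
#' @param lambda_heights internal depth of each Lambda subnetwork by stage;
#'   default the mirror `2, 3, ..., L+1` (the deepest stage, applied first,
#'   receives the largest depth `L+1`), so each Lambda crests at `2 H`.
#' @param residuals_enabled enable the identity (residual) connection inside
#'   every subnetwork; the ablation harness turns this off.
#' @return a `wavenet_config` object with `side_outputs = L + 1` (four side
#'   outputs, hence four BCE terms, at the reference depth L = 3).
#' @export
wavenet_config <- function(L = 3L, base_channels = 32L,
                           channel_schedule = NULL,
                           v_heights = NULL, lambda_heights = NULL,
                           residuals_enabled = TRUE) {
  L <- as.integer(L)
  if (!(L %in% 3:5)) stop("L must be 3, 4 or 5")
  C0 <- as.integer(base_channels)
  stopifnot(C0 >= 1)
  if (is.null(channel_schedule))
    channel_schedule <- pmin(C0 * 2^(seq_len(L) - 1L), 8L * C0)
  channel_schedule <- as.integer(channel_schedule)
  stopifnot(length(channel_schedule) == L, all(channel_schedule >= 1))
  if (is.null(v_heights)) v_heights <- seq(L + 1L, 2L)
  v_heights <- as.integer(v_heights)
  if (length(v_heights) != L || any(diff(v_heights) >= 0) || any(v_heights < 2))
    stop("v_heights must be strictly decreasing with all entries >= 2")
  if (is.null(lambda_heights)) lambda_heights <- rev(v_heights)
  lambda_heights <- as.integer(lambda_heights)
  if (length(lambda_heights) != L || any(lambda_heights < 2))
    stop("lambda_heights must have length L with all entries >= 2")
  cfg <- list(L = L, base_channels = C0, channel_schedule = channel_schedule,
              v_heights = v_heights, lambda_heights = lambda_heights,
              residuals_enabled = isTRUE(residuals_enabled),
              side_outputs = L + 1L)
  class(cfg) <- "wavenet_config"
  cfg
}

#' @export
print.wavenet_config <- function(x, ...) {
  cat(sprintf("wavenet_config: W-%d, channels [%s], residuals %s\n",
              x$L, paste(x$channel_schedule, collapse = ", "),
              if (x$residuals_enabled) "on" else "off"))
  cat(sprintf("  V heights [%s], Lambda heights [%s], %d side outputs\n",
              paste(x$v_heights, collapse = ", "),
              paste(x$lambda_heights, collapse = ", "), x$side_outputs))
  invisible(x)
}

# ---- building blocks -------------------------------------------------------

new_param <- function(dimv, sd) {
  v <- stats::rnorm(prod(dimv), 0, sd)
  new_tensor(if (length(dimv) > 1) array(v, dimv) else v, requires_grad = TRUE)
}

new_bn_state <- function(cout) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(cout)
  e$running_var <- rep(1, cout)
  e
}

# one DWC unit: depthwise 3x3 -> pointwise 1x1 -> batch norm -> SiLU
new_conv_unit <- function(cin, cout) {
  structure(list(
    dw_w = new_param(c(3, 3, cin), sqrt(2 / 9)),
    dw_b = new_tensor(numeric(cin), requires_grad = TRUE),
    pw_w = new_param(c(cin, cout), sqrt(2 / cin)),
    pw_b = new_tensor(numeric(cout), requires_grad = TRUE),
    bn_gamma = new_tensor(rep(1, cout), requires_grad = TRUE),
    bn_beta = new_tensor(numeric(cout), requires_grad = TRUE),
    bn_state = new_bn_state(cout),
    cin = cin, cout = cout), class = "wn_conv_unit")
}

fwd_conv_unit <- function(m, x, training) {
  h <- op_dwconv3(x, m$dw_w, m$dw_b)
  h <- op_conv1x1(h, m$pw_w, m$pw_b)
  h <- op_batchnorm(h, m$bn_gamma, m$bn_beta, m$bn_state, training = training)
  op_silu(h)
}

new_proj <- function(cin, cout) {
  list(w = new_param(c(cin, cout), 1 / sqrt(cin)),
       b = new_tensor(numeric(cout), requires_grad = TRUE))
}

# V-shaped subnetwork: height-1 encode steps (conv then 2x2 max-pool), a
# bottom conv, height-1 decode steps (bilinear 2x up-sample then conv) with
# identical-scale concatenation, and an optional residual identity/projection.
new_v_subnet <- function(height, cin, mid, cout, residual) {
  stopifnot(height >= 2)
  enc <- lapply(seq_len(height - 1L), function(j)
    new_conv_unit(if (j == 1L) cin else mid, mid))
  dec <- lapply(seq_len(height - 1L), function(k)
    new_conv_unit(2L * mid, if (k == height - 1L) cout else mid))
  structure(list(enc = enc, bottom = new_conv_unit(mid, mid), dec = dec,
                 proj = if (residual && cin != cout) new_proj(cin, cout) else NULL,
                 residual = residual, height = height,
                 cin = cin, cout = cout), class = "wn_v_subnet")
}

fwd_v_subnet <- function(m, x, training) {
  h <- m$height
  skips <- vector("list", h - 1L)
  cur <- x
  for (j in seq_len(h - 1L)) {
    skips[[j]] <- fwd_conv_unit(m$enc[[j]], cur, training)
    cur <- op_maxpool2(skips[[j]])
  }
  cur <- fwd_conv_unit(m$bottom, cur, training)
  k <- 0L
  for (j in seq(h - 1L, 1L)) {
    k <- k + 1L
    cur <- op_upsample2(cur)
    cur <- fwd_conv_unit(m$dec[[k]], op_concat(list(cur, skips[[j]])), training)
  }
  if (m$residual) {
    r <- if (is.null(m$proj)) x else op_conv1x1(x, m$proj$w, m$proj$b)
    cur <- op_add(cur, r)
  }
  cur
}

# Lambda-shaped subnetwork: height-1 expand steps (bilinear 2x up-sample then
# conv) followed by height-1 reduce steps (conv then 2x2 max-pool) with
# identical-scale concatenation between the two paths; optional residual.
new_lambda_subnet <- function(height, cin, mid, cout, residual) {
  stopifnot(height >= 2)
  expd <- lapply(seq_len(height - 1L), function(j)
    new_conv_unit(if (j == 1L) cin else mid, mid))
  red <- lapply(seq_len(height - 1L), function(k)
    new_conv_unit(if (k == 1L) mid else 2L * mid,
                  if (k == height - 1L) cout else mid))
  structure(list(expd = expd, red = red,
                 proj = if (residual && cin != cout) new_proj(cin, cout) else NULL,
                 residual = residual, height = height,
                 cin = cin, cout = cout), class = "wn_lambda_subnet")
}

fwd_lambda_subnet <- function(m, x, training) {
  h <- m$height
  es <- vector("list", h - 1L)
  cur <- x
  for (j in seq_len(h - 1L)) {
    cur <- fwd_conv_unit(m$expd[[j]], op_upsample2(cur), training)
    es[[j]] <- cur
  }
  cur <- op_maxpool2(fwd_conv_unit(m$red[[1L]], cur, training))
  if (h >= 3L) {
    k <- 1L
    for (j in seq(h - 2L, 1L)) {
      k <- k + 1L
      cur <- op_maxpool2(
        fwd_conv_unit(m$red[[k]], op_concat(list(cur, es[[j]])), training))
    }
  }
  if (m$residual) {
    r <- if (is.null(m$proj)) x else op_conv1x1(x, m$proj$w, m$proj$b)
    cur <- op_add(cur, r)
  }
  cur
}

# ---- full model ------------------------------------------------------------

#' Build a Wave-Net model
#'
#' Instantiates the aggregation stages `V_1..V_L` (2x2 max-pool between
#' stages), the dispersion stages `Lambda_L..Lambda_1` (bilinear 2x up-sample
#' between stages), one 1x1-conv + sigmoid head per fused scale, a final
#' full-resolution head on the last dispersion output, and the 1x1 fusion
#' head over the concatenated side maps. Parameter initialization is
#' reproducible from `seed`.
#'
#' @param config a [wavenet_config()].
#' @param seed integer seed for weight initialization.
#' @return a `wavenet_model`.
#' @export
build_wavenet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "wavenet_config"))
  with_seed(seed, {
    L <- config$L
    ch <- config$channel_schedule
    res <- config$residuals_enabled
    stages <- vector("list", L)
    for (i in seq_len(L)) {
      stages[[i]] <- list(
        v = new_v_subnet(config$v_heights[i],
                         cin = if (i == 1L) 1L else ch[i - 1L],
                         mid = ch[i], cout = ch[i], residual = res),
        lambda = new_lambda_subnet(config$lambda_heights[i],
                                   cin = if (i == L) ch[L] else ch[i + 1L],
                                   mid = ch[i], cout = ch[i], residual = res))
    }
    heads <- lapply(seq_len(L), function(i) new_proj(2L * ch[i], 1L))
    head_final <- new_proj(ch[1L], 1L)
    S <- config$side_outputs
    fuse <- list(w = new_tensor(matrix(4 / S, S, 1L), requires_grad = TRUE),
                 b = new_tensor(-2, requires_grad = TRUE))
    model <- list(config = config, stages = stages, heads = heads,
                  head_final = head_final, fuse = fuse, seed = as.integer(seed))
    class(model) <- "wavenet_model"
    model
  })
}

#' @export
print.wavenet_model <- function(x, ...) {
  cat(sprintf("wavenet_model: W-%d, %s trainable parameters (seed %d)\n",
              x$config$L, format(count_parameters(x), big.mark = ","), x$seed))
  print(x$config)
  invisible(x)
}

# smallest multiple of 2^L at or above n
padded_size <- function(n, L) as.integer(ceiling(n / 2^L) * 2^L)

check_input_size <- function(H, W, L) {
  f <- 2^L
  if (H %% f != 0L || W %% f != 0L)
    stop(sprintf(paste0("input size %dx%d is not divisible by 2^L = %d; ",
                        "smallest valid padded size is %dx%d"),
                 H, W, f, padded_size(H, L), padded_size(W, L)))
}

# internal forward on a tensor (H, W, 1, N); returns tensors
forward_wavenet_t <- function(model, x, training = FALSE) {
  d <- dims4(x)
  L <- model$config$L
  check_input_size(d[1], d[2], L)
  a <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    a[[i]] <- fwd_v_subnet(model$stages[[i]]$v, cur, training)
    if (i < L) cur <- op_maxpool2(a[[i]])
  }
  z <- vector("list", L)
  cur <- a[[L]]
  for (i in seq(L, 1L)) {
    z[[i]] <- fwd_lambda_subnet(model$stages[[i]]$lambda, cur, training)
    cur <- if (i > 1L) op_upsample2(z[[i]]) else z[[i]]
  }
  side <- vector("list", L + 1L)
  for (i in seq_len(L)) {
    f <- op_concat(list(a[[i]], z[[i]]))
    p <- op_sigmoid(op_conv1x1(f, model$heads[[i]]$w, model$heads[[i]]$b))
    for (k in seq_len(i - 1L)) p <- op_upsample2(p)
    side[[i]] <- p
  }
  side[[L + 1L]] <- op_sigmoid(
    op_conv1x1(z[[1L]], model$head_final$w, model$head_final$b))
  fused <- op_sigmoid(op_conv1x1(op_concat(side), model$fuse$w, model$fuse$b))
  list(side = side, fused = fused)
}

# coerce user input to an (H, W, 1, N) array
as_batch_array <- function(images) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L, 1L))
  else if (length(dim(images)) == 3L)
    images <- array(images, c(dim(images)[1:2], 1L, dim(images)[3]))
  stopifnot(length(dim(images)) == 4L, dim(images)[3] == 1L)
  images
}

#' Run a forward pass
#'
#' @param model a `wavenet_model`.
#' @param images a matrix (one tile), an `(H, W, N)` array, or an
#'   `(H, W, 1, N)` array of normalized tiles. Spatial dimensions must be
#'   divisible by `2^L`.
#' @return a `wn_segoutput` with `side_maps` (list of `S = L + 1` probability
#'   arrays, each at the input resolution) and `fused_map`; all values lie
#'   strictly in (0, 1). Single-tile input gives matrices.
#' @export
wn_forward <- function(model, images) {
  stopifnot(inherits(model, "wavenet_model"))
  single <- is.matrix(images)
  x <- new_tensor(as_batch_array(images))
  out <- with_no_grad(forward_wavenet_t(model, x, training = FALSE))
  squeeze <- function(t) {
    v <- t$value
    if (single) matrix(v, dim(v)[1], dim(v)[2])
    else array(v, dim(v)[c(1, 2, 4)])
  }
  structure(list(side_maps = lapply(out$side, squeeze),
                 fused_map = squeeze(out$fused)),
            class = "wn_segoutput")
}

#' Count trainable parameters
#' @param model a `wavenet_model` (or any nested structure of tensors).
#' @return integer scalar count of trainable values.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$value), numeric(1)))
}

# depth-first collection of trainable tensors, in deterministic order
collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (is_tensor(e)) {
      if (isTRUE(e$requires_grad)) out[[length(out) + 1L]] <<- e
    } else if (is.list(e)) {
      for (el in e) walk(el)
    }
  }
  walk(x)
  out
}

collect_bn_states <- function(x) {
  out <- list()
  walk <- function(e) {
    if (inherits(e, "wn_conv_unit")) {
      out[[length(out) + 1L]] <<- e$bn_state
      for (el in e) walk(el)
    } else if (is.list(e)) for (el in e) walk(el)
  }
  walk(x)
  out
}

# snapshot / restore of all learnable state (weights + BN running stats)
model_state <- function(model) {
  list(params = lapply(collect_params(model), function(p) p$value),
       bn = lapply(collect_bn_states(model), function(s)
         list(mean = s$running_mean, var = s$running_var)))
}

restore_state <- function(model, state) {
  ps <- collect_params(model)
  stopifnot(length(ps) == length(state$params))
  for (i in seq_along(ps)) ps[[i]]$value <- state$params[[i]]
  bs <- collect_bn_states(model)
  for (i in seq_along(bs)) {
    bs[[i]]$running_mean <- state$bn[[i]]$mean
    bs[[i]]$running_var <- state$bn[[i]]$var
  }
  invisible(model)
}

#' Save / load a Wave-Net checkpoint
#'
#' Checkpoints embed the architecture config and seed, so loading rebuilds
#' the model and restores every weight and batch-norm statistic.
#'
#' @param model a `wavenet_model`.
#' @param path checkpoint file (RDS).
#' @return `save_wavenet`: `path`, invisibly; `load_wavenet`: the model.
#' @export
save_wavenet <- function(model, path) {
  stopifnot(inherits(model, "wavenet_model"))
  saveRDS(list(config = model$config, seed = model$seed,
               state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_wavenet
#' @export
load_wavenet <- function(path) {
  ck <- readRDS(path)
  model <- build_wavenet(ck$config, seed = ck$seed)
  restore_state(model, ck$state)
  model
}

#' Read a Wave-Net architecture config from YAML
#'
#' Recognized keys: `L`, `base_channels`, `channel_schedule`, `v_heights`,
#' `lambda_heights`, `residuals_enabled`.
#' @param path YAML file.
#' @return a `wavenet_config`.
#' @export
wavenet_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(wavenet_config, y)
}
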