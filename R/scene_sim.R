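#' Parameters for a synthetic SAR aquaculture scene
#'
#' Describes a sea-clutter background with groups of parallel rectangular
#' rafts, observed in linear backscatter intensity under fully developed
#' multiplicative speckle. Defaults emulate a Sentinel-1-like GRD VV scene at
#' ~10 m pixels: dim sea surface, rafts about four times brighter, ENL 4.
#'
#' @param height_px,width_px raster dimensions in pixels.
#' @param sea_level mean sea backscatter, linear units, > 0.
#' @param raft_level mean raft backscatter, linear units, > 0. May be below
#'   `sea_level` for dark-raft polarity.
#' @param enl equivalent number of looks (>= 1), or the string `"no-speckle"`
#'   (equivalently `Inf`) for a noise-free scene. The speckle coefficient of
#'   variation is `1/sqrt(enl)`.
#' @param n_raft_groups number of raft groups to place (>= 0). Each group is a
#'   set of parallel rectangular rafts sharing one orientation.
#' @param raft_length_px,raft_width_px,raft_gap_px length-2 ranges (pixels)
#'   from which each group's raft length, width and inter-raft gap are drawn.
#' @param rafts_per_group length-2 range for the number of rafts in a group.
#' @param orientation_deg length-2 range (degrees) for group orientation.
#' @param seed integer seed controlling layout and speckle.
#' @return a `scene_params` object.
#' @export
scene_params <- function(height_px = 512, width_px = 512,
                         sea_level = 0.03, raft_level = 0.12,
                         enl = 4,
                         n_raft_groups = 8,
                         raft_length_px = c(24, 64),
                         raft_width_px = c(4, 9),
                         raft_gap_px = c(3, 7),
                         rafts_per_group = c(3, 8),
                         orientation_deg = c(0, 180),
                         seed = 1L) {
  stopifnot(height_px >= 1, width_px >= 1)
  if (!(sea_level > 0) || !(raft_level > 0))
    stop("intensity levels must be strictly positive")
  enl <- check_enl(enl)
  stopifnot(n_raft_groups >= 0, length(raft_length_px) == 2,
            length(raft_width_px) == 2, length(raft_gap_px) == 2,
            length(orientation_deg) == 2, length(rafts_per_group) == 2)
  p <- list(height_px = as.integer(height_px), width_px = as.integer(width_px),
            sea_level = sea_level, raft_level = raft_level, enl = enl,
            n_raft_groups = as.integer(n_raft_groups),
            raft_length_px = raft_length_px, raft_width_px = raft_width_px,
            raft_gap_px = raft_gap_px,
            rafts_per_group = as.integer(rafts_per_group),
            orientation_deg = orientation_deg, seed = as.integer(seed))
  class(p) <- "scene_params"
  p
}

check_enl <- function(enl) {
  if (identical(enl, "no-speckle")) return(Inf)
  if (!is.numeric(enl) || length(enl) != 1 || is.na(enl) || enl < 1)
    stop("enl must be a number >= 1 or \"no-speckle\"")
  enl
}

# pixel-center coordinates of one rotated rectangle's interior, clipped test
# done over its bounding box only. Returns an integer matrix (row, col),
# 1-based, or NULL when the rectangle does not fit inside the raster.
rect_pixels <- function(cy, cx, len, wid, theta_deg, H, W) {
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th))    # along-length axis (row, col)
  v <- c(-sin(th), cos(th))   # along-width axis
  hl <- len / 2; hw <- wid / 2
  corners_r <- cy + c(-1, -1, 1, 1) * hl * u[1] + c(-1, 1, -1, 1) * hw * v[1]
  corners_c <- cx + c(-1, -1, 1, 1) * hl * u[2] + c(-1, 1, -1, 1) * hw * v[2]
  if (min(corners_r) < 0 || max(corners_r) > H ||
      min(corners_c) < 0 || max(corners_c) > W) return(NULL)
  r0 <- max(1L, floor(min(corners_r)) + 1L); r1 <- min(H, ceiling(max(corners_r)))
  c0 <- max(1L, floor(min(corners_c)) + 1L); c1 <- min(W, ceiling(max(corners_c)))
  if (r1 < r0 || c1 < c0) return(NULL)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  # center-of-pixel inclusion test in the rectangle frame
  dy <- (rr - 0.5) - cy
  dx <- (cc - 0.5) - cx
  pu <- dy * u[1] + dx * u[2]
  pv <- dy * v[1] + dx * v[2]
  keep <- abs(pu) <= hl & abs(pv) <= hw
  cbind(rr[keep], cc[keep])
}

#' Rasterize a raft layout into a clean reflectivity map and truth mask
#'
#' Places `n_raft_groups` groups of parallel rafts uniformly at random (drawn
#' from the parameter ranges) so that every raft lies fully inside the raster;
#' a group that cannot be placed after a bounded number of attempts is skipped
#' with a message. Masks are exact: a pixel is raft iff its center falls
#' inside a raft rectangle.
#'
#' @param params a [scene_params()] object.
#' @return list with `clean` (matrix of linear reflectivity) and `mask`
#'   (binary matrix, 1 = raft).
#' @export
rasterize_layout <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  H <- params$height_px; W <- params$width_px
  clean <- matrix(params$sea_level, H, W)
  mask <- matrix(0L, H, W)
  if (params$n_raft_groups == 0L)
    return(list(clean = clean, mask = mask))
  with_seed(params$seed, {
    for (g in seq_len(params$n_raft_groups)) {
      placed <- FALSE
      for (try in 1:25) {
        len <- runif(1, params$raft_length_px[1], params$raft_length_px[2])
        wid <- runif(1, params$raft_width_px[1], params$raft_width_px[2])
        gap <- runif(1, params$raft_gap_px[1], params$raft_gap_px[2])
        k <- sample(params$rafts_per_group[1]:params$rafts_per_group[2], 1)
        th <- runif(1, params$orientation_deg[1], params$orientation_deg[2])
        cy <- runif(1, 0, H); cx <- runif(1, 0, W)
        # rafts laid side by side along the width axis
        v <- c(-sin(th * pi / 180), cos(th * pi / 180))
        offs <- (seq_len(k) - (k + 1) / 2) * (wid + gap)
        pix <- vector("list", k)
        ok <- TRUE
        for (m in seq_len(k)) {
          p <- rect_pixels(cy + offs[m] * v[1], cx + offs[m] * v[2],
                           len, wid, th, H, W)
          if (is.null(p)) { ok <- FALSE; break }
          pix[[m]] <- p
        }
        if (ok) {
          for (p in pix) if (nrow(p) > 0) mask[p] <- 1L
          placed <- TRUE
          break
        }
      }
      if (!placed)
        message("raft group ", g, " could not be placed inside the raster; skipped")
    }
  })
  clean[mask == 1L] <- params$raft_level
  list(clean = clean, mask = mask)
}

#' Apply fully developed multiplicative gamma speckle
#'
#' Each pixel is multiplied by an independent gamma variate with shape `enl`
#' and mean 1, the standard model for multi-looked SAR intensity: regional
#' means are preserved and the coefficient of variation of a homogeneous
#' region is `1/sqrt(enl)`.
#'
#' @param clean non-negative matrix of linear reflectivity.
#' @param enl equivalent number of looks (>= 1), `Inf` or `"no-speckle"` for
#'   an identity pass-through.
#' @param seed integer seed.
#' @return matrix of speckled intensity, same shape as `clean`.
#' @export
apply_speckle <- function(clean, enl, seed = 1L) {
  if (any(clean < 0)) stop("clean reflectivity must be non-negative")
  enl <- check_enl(enl)
  if (is.infinite(enl)) return(clean)
  with_seed(seed, {
    noise <- matrix(stats::rgamma(length(clean), shape = enl, rate = enl),
                    nrow(clean), ncol(clean))
    clean * noise
  })
}

#' Simulate a complete speckled SAR scene with exact ground truth
#'
#' Composes [rasterize_layout()] and [apply_speckle()]; fully reproducible
#' from `params$seed` (layout and speckle use decoupled derived seeds).
#'
#' @param params a [scene_params()] object.
#' @return a `sar_scene` object: `intensity` (matrix), `mask` (binary
#'   matrix), `params`.
#' @export
simulate_scene <- function(params) {
  lay <- rasterize_layout(params)
  intensity <- apply_speckle(lay$clean, params$enl,
                             seed = (params$seed + 7919L) %% .Machine$integer.max)
  scene <- list(intensity = intensity, mask = lay$mask, params = params)
  class(scene) <- "sar_scene"
  scene
}

#' @export
print.sar_scene <- function(x, ...) {
  p <- x$params
  cat(sprintf("sar_scene: %d x %d px, %d raft group(s) requested, ENL %s\n",
              p$height_px, p$width_px, p$n_raft_groups,
              if (is.infinite(p$enl)) "none (no speckle)" else format(p$enl)))
  cat(sprintf("  raft fraction %.3f; intensity range [%.4g, %.4g] (linear)\n",
              mean(x$mask), min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Convert linear intensity to a dB view for display
#' @param intensity matrix of linear backscatter (> 0 where defined).
#' @param floor_db values are floored here after conversion.
#' @return matrix in decibels.
#' @export
intensity_to_db <- function(intensity, floor_db = -40) {
  pmax(10 * log10(pmax(intensity, 1e-12)), floor_db)
}
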