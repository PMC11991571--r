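#' Refined Lee filter parameters
#'
#' @param window odd window size >= 3 (default 7, the size used throughout the
#'   preprocessing pipeline).
#' @param enl equivalent number of looks of the input, used to set the speckle
#'   coefficient of variation `Cu = 1/sqrt(enl)`; `NULL` to estimate `Cu` from
#'   the image as the minimum local coefficient of variation (classical
#'   homogeneous-area heuristic).
#' @return a `lee_params` object.
#' @export
lee_params <- function(window = 7L, enl = NULL) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (!is.null(enl)) {
    if (!is.numeric(enl) || enl < 1) stop("enl must be >= 1")
  }
  structure(list(window = window, enl = enl), class = "lee_params")
}

#' Refined Lee adaptive despeckling
#'
#' Edge-preserving MMSE speckle filter: at each pixel a 3x3 template of
#' sub-window means estimates the dominant local gradient direction; one of
#' eight edge-aligned half-windows is selected (on the side whose mean is
#' closest to the center sub-window mean) and the minimum-mean-square-error
#' weighting `x_hat = m + k (y - m)` is applied with
#' `k = clamp((var - m^2 Cu^2) / ((1 + Cu^2) var), 0, 1)` computed from the
#' half-window statistics. Borders are reflect-padded so the output has the
#' input's shape; `k` clamped to `[0, 1]` makes every output pixel a convex
#' combination of the half-window mean and the center pixel, hence bounded by
#' the local window extremes. A zero-variance window yields `k = 0` (local
#' mean, no division error), so constant images are reproduced exactly.
#'
#' @param image non-negative matrix of linear intensity.
#' @param params a [lee_params()] object (or window size for convenience).
#' @return filtered matrix, same shape.
#' @export
refined_lee <- function(image, params = lee_params()) {
  if (is.numeric(params) && length(params) == 1) params <- lee_params(params)
  stopifnot(inherits(params, "lee_params"), is.matrix(image))
  if (any(image < 0)) stop("image must be non-negative linear intensity")
  if (min(dim(image)) <= params$window)
    stop("image must be larger than the filter window")
  cu2 <- if (is.null(params$enl)) estimate_cu2(image, params$window)
         else 1 / params$enl
  cpp_refined_lee(image, params$window, cu2)
}

# Cu^2 estimate: minimum local squared coefficient of variation over pixels
# with positive local mean (homogeneous-area heuristic).
estimate_cu2 <- function(image, window = 7L) {
  st <- cpp_local_stats(image, as.integer(window))
  ok <- st$mean > 0 & st$var > 0
  if (!any(ok)) return(0)
  min(st$var[ok] / st$mean[ok]^2)
}

#' Plain boxcar (moving-average) filter
#'
#' Non-adaptive local mean with reflect padding; the classical baseline a
#' despeckler must beat near edges.
#'
#' @param image matrix.
#' @param window odd window size.
#' @return filtered matrix, same shape.
#' @export
boxcar_mean <- function(image, window = 7L) {
  cpp_local_stats(image, as.integer(window))$mean
}
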