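# Tiling, dihedral augmentation, leakage-safe splitting and tile
# normalization for image/mask pairs.

new_tile <- function(image, mask, origin, transform_tag = "identity",
                     source_id = NA_integer_) {
  structure(list(image = image, mask = mask, origin = as.integer(origin),
                 transform_tag = transform_tag,
                 source_id = as.integer(source_id)),
            class = "wn_tile")
}

new_tileset <- function(tiles, split_labels = NULL, seed = NA_integer_) {
  structure(list(tiles = tiles, split_labels = split_labels,
                 seed = as.integer(seed)),
            class = "wn_tileset")
}

#' @export
print.wn_tileset <- function(x, ...) {
  cat(sprintf("wn_tileset: %d tile(s)", length(x$tiles)))
  if (length(x$tiles) > 0) {
    d <- dim(x$tiles[[1]]$image)
    cat(sprintf(" of %d x %d", d[1], d[2]))
  }
  if (!is.null(x$split_labels)) {
    tb <- table(factor(x$split_labels, levels = c("train", "val", "test")))
    cat(sprintf("; splits train/val/test = %d/%d/%d",
                tb[["train"]], tb[["val"]], tb[["test"]]))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.wn_tileset <- function(x) length(x$tiles)

#' Cut an image/mask pair into fixed-size tiles
#'
#' Regular grid in row-major order; origins are 0-based offsets into the
#' source; partial tiles at the right/bottom edges are discarded. With
#' `stride = tile_size` the grid is non-overlapping.
#'
#' @param image numeric matrix.
#' @param mask binary matrix, same shape (values in \{0,1\} or \{0,255\};
#'   anything > 0 is foreground).
#' @param tile_size tile side length in pixels.
#' @param stride grid step (default `tile_size`).
#' @return a `wn_tileset` with untransformed tiles.
#' @export
tile_scene <- function(image, mask, tile_size, stride = tile_size) {
  stopifnot(is.matrix(image), is.matrix(mask), all(dim(image) == dim(mask)),
            tile_size >= 1, stride >= 1)
  if (tile_size > max(dim(image)))
    stop("tile_size (", tile_size, ") exceeds both image dimensions (",
         paste(dim(image), collapse = "x"), ")")
  mask <- binarize_mask(mask)
  if (tile_size > min(dim(image)))   # fits one dimension only: no full tiles
    return(new_tileset(list()))
  rows <- seq(0L, nrow(image) - tile_size, by = stride)
  cols <- seq(0L, ncol(image) - tile_size, by = stride)
  tiles <- vector("list", length(rows) * length(cols))
  k <- 0L
  for (r in rows) for (cl in cols) {
    k <- k + 1L
    tiles[[k]] <- new_tile(image[r + seq_len(tile_size), cl + seq_len(tile_size)],
                           mask[r + seq_len(tile_size), cl + seq_len(tile_size)],
                           origin = c(r, cl), source_id = k)
  }
  new_tileset(tiles)
}

binarize_mask <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  m
}

# The six dihedral operators used for augmentation: the flips/mirrors of the
# square (no +/-90 deg rotations), plus identity.
aug_transforms <- c("identity", "hflip", "vflip", "rot180",
                    "transpose", "antitranspose")

apply_transform <- function(x, tag) {
  switch(tag,
    identity = x,
    hflip = x[, rev(seq_len(ncol(x))), drop = FALSE],
    vflip = x[rev(seq_len(nrow(x))), , drop = FALSE],
    rot180 = x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE],
    transpose = t(x),
    antitranspose = t(x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE]),
    stop("unknown transform tag: ", tag)
  )
}

#' Expand a tile set six-fold by flip/mirror augmentation
#'
#' Every source tile yields exactly six samples — identity, horizontal flip,
#' vertical flip, 180-degree rotation, main-diagonal mirror (transpose) and
#' anti-diagonal mirror — with image and mask transformed identically. The
#' factor six reproduces the sample expansion of the reference pipeline
#' (685 blocks to 4110 samples). Split labels, when present, are inherited
#' from the source tile so augmented variants never straddle splits.
#'
#' @param tileset a `wn_tileset` of untransformed tiles.
#' @return a `wn_tileset` with `6 * length(tileset)` tiles.
#' @export
augment_tiles <- function(tileset) {
  stopifnot(inherits(tileset, "wn_tileset"))
  if (!all(vapply(tileset$tiles, function(t) t$transform_tag, "") == "identity"))
    stop("augment_tiles expects untransformed input tiles")
  out <- vector("list", 6L * length(tileset$tiles))
  labs <- if (!is.null(tileset$split_labels))
    character(6L * length(tileset$tiles)) else NULL
  k <- 0L
  for (i in seq_along(tileset$tiles)) {
    t0 <- tileset$tiles[[i]]
    for (tag in aug_transforms) {
      k <- k + 1L
      out[[k]] <- new_tile(apply_transform(t0$image, tag),
                           apply_transform(t0$mask, tag),
                           origin = t0$origin, transform_tag = tag,
                           source_id = t0$source_id)
      if (!is.null(labs)) labs[k] <- tileset$split_labels[i]
    }
  }
  new_tileset(out, split_labels = labs, seed = tileset$seed)
}

#' Partition tiles into train/validation/test sets
#'
#' Uniform random partition of *source* tiles at the given proportions
#' (largest-remainder rounding), reproducible from `seed`. All augmented
#' variants of one source tile receive the same label, so augmentation and
#' splitting commute without leakage.
#'
#' @param tileset a `wn_tileset`.
#' @param ratios positive length-3 weights for train/val/test (default 3:1:1).
#' @param seed integer seed.
#' @return the tile set with `split_labels` filled in.
#' @export
split_tiles <- function(tileset, ratios = c(3, 1, 1), seed = 1L) {
  stopifnot(inherits(tileset, "wn_tileset"), length(ratios) == 3, all(ratios > 0))
  src <- vapply(tileset$tiles, function(t) t$source_id, integer(1))
  usrc <- sort(unique(src))
  n <- length(usrc)
  if (n < 3L) stop("need at least 3 source tiles to form 3 splits")
  # largest-remainder apportionment
  quota <- n * ratios / sum(ratios)
  base <- floor(quota)
  rem <- quota - base
  extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
  counts <- base
  counts[extra] <- counts[extra] + 1L
  labels <- rep(c("train", "val", "test"), times = counts)
  perm <- with_seed(seed, sample.int(n))
  src_label <- character(n)
  src_label[perm] <- labels
  names(src_label) <- as.character(usrc)
  tileset$split_labels <- unname(src_label[as.character(src)])
  tileset$seed <- as.integer(seed)
  tileset
}

#' Pick the network depth L from the tile size
#'
#' Sample-size to architecture mapping: `[300, 400) -> L = 3`,
#' `[400, 500) -> L = 4`, `[500, 600] -> L = 5` (intervals half-open on the
#' left shared endpoint). 320-pixel tiles, the pipeline default, select L = 3.
#'
#' @param tile_size tile side length in pixels.
#' @return integer L in \{3, 4, 5\}.
#' @export
select_architecture <- function(tile_size) {
  s <- as.numeric(tile_size)
  if (length(s) != 1 || is.na(s) || s < 300 || s > 600)
    stop("tile size ", tile_size, " is outside [300, 600]; ",
         "choose L manually via wavenet_config(L = ...)")
  if (s < 400) 3L else if (s < 500) 4L else 5L
}

#' Min-max normalize a tile to [0, 1]
#'
#' Per-tile linear rescaling; a constant tile maps to all zeros. Idempotent.
#'
#' @param image numeric matrix (finite values).
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_tile <- function(image) {
  if (!all(is.finite(image))) stop("tile contains non-finite values")
  rg <- range(image)
  if (rg[2] == rg[1]) return(matrix(0, nrow(image), ncol(image)))
  (image - rg[1]) / (rg[2] - rg[1])
}

# tiles of one split, as a list
split_subset <- function(tileset, which) {
  if (is.null(tileset$split_labels)) stop("tile set has no split labels")
  tileset$tiles[tileset$split_labels == which]
}

# stack a list of tiles into (H, W, 1, N) image batch + (H, W, 1, N) masks,
# min-max normalizing each image tile
tiles_to_batch <- function(tiles) {
  stopifnot(length(tiles) > 0)
  d <- dim(tiles[[1]]$image)
  x <- array(0, c(d[1], d[2], 1, length(tiles)))
  y <- array(0, c(d[1], d[2], 1, length(tiles)))
  for (i in seq_along(tiles)) {
    x[, , 1, i] <- normalize_tile(tiles[[i]]$image)
    y[, , 1, i] <- tiles[[i]]$mask
  }
  list(x = x, y = y)
}
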