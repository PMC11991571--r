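# Raster and tile-store I/O.
#
# Images travel as plain single-band TIFF (32-bit float) or PNG (8-bit).
# TIFF storage holds values in [0, 1]; linear intensities are therefore
# written divided by a scale factor recorded in a JSON sidecar
# (`<file>.json`), and multiplied back on read. Masks are stored as 8-bit
# {0, 1} rasters and re-binarized (> 0) on read.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a single-band raster
#'
#' @param x numeric matrix. For TIFF, values are scaled into `[0, 1]` by
#'   `scale` (default: the matrix maximum) which is recorded in a JSON
#'   sidecar; for PNG, values are min-max scaled to 8 bits.
#' @param path output file; extension selects the format (`.tif`/`.tiff` or
#'   `.png`).
#' @param scale optional fixed scale for TIFF storage.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, scale = NULL) {
  stopifnot(is.matrix(x))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(scale)) scale <- max(x, 1e-12)
    tiff::writeTIFF(pmin(pmax(x / scale, 0), 1), path, bits.per.sample = 32L)
    jsonlite::write_json(list(intensity_scale = scale),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else if (ext == "png") {
    rg <- range(x)
    y <- if (rg[2] > rg[1]) (x - rg[1]) / (rg[2] - rg[1]) else x * 0
    png::writePNG(y, path)
  } else stop("unsupported raster extension: .", ext)
  invisible(path)
}

#' Read a single-band raster written by [write_raster()] (or any grayscale
#' TIFF/PNG)
#'
#' @param path input file.
#' @return numeric matrix; TIFF values are multiplied by the sidecar scale
#'   when one is present.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else if (ext == "png") png::readPNG(path)
       else stop("unsupported raster extension: .", ext)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  sc <- sidecar_path(path)
  if (ext %in% c("tif", "tiff") && file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$intensity_scale)) x <- x * as.numeric(meta$intensity_scale)
  }
  x
}

#' Write a simulated scene to disk
#'
#' Stores `intensity.tif` (float, sidecar-scaled), `mask.tif` (8-bit 0/1) and
#' `params.json` in `dir`.
#'
#' @param scene a `sar_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "sar_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(scene$intensity, file.path(dir, "intensity.tif"))
  tiff::writeTIFF(scene$mask + 0, file.path(dir, "mask.tif"), bits.per.sample = 8L)
  p <- scene$params
  p$enl <- if (is.infinite(p$enl)) "no-speckle" else p$enl
  jsonlite::write_json(unclass(p), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#' @param dir scene directory.
#' @return a `sar_scene`.
#' @export
read_scene <- function(dir) {
  intensity <- read_raster(file.path(dir, "intensity.tif"))
  mask <- binarize_mask(tiff::readTIFF(file.path(dir, "mask.tif")))
  pj <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- do.call(scene_params, pj[setdiff(names(pj), character(0))])
  structure(list(intensity = intensity, mask = mask, params = params),
            class = "sar_scene")
}

#' Write a tile set to an on-disk store
#'
#' One directory per split (or `all/` when the set is unsplit) with
#' `img_%05d.tif` / `msk_%05d.tif` pairs, plus `manifest.json` recording
#' origins, transforms, source ids, split labels and the split seed.
#'
#' @param tileset a `wn_tileset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tileset <- function(tileset, dir) {
  stopifnot(inherits(tileset, "wn_tileset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- tileset$split_labels
  if (is.null(labs)) labs <- rep("all", length(tileset$tiles))
  rows <- vector("list", length(tileset$tiles))
  for (i in seq_along(tileset$tiles)) {
    t <- tileset$tiles[[i]]
    sub <- file.path(dir, labs[i])
    dir.create(sub, showWarnings = FALSE)
    img <- sprintf("img_%05d.tif", i)
    msk <- sprintf("msk_%05d.tif", i)
    write_raster(t$image, file.path(sub, img))
    tiff::writeTIFF(t$mask + 0, file.path(sub, msk), bits.per.sample = 8L)
    rows[[i]] <- list(index = i, split = labs[i], image = file.path(labs[i], img),
                      mask = file.path(labs[i], msk), origin = t$origin,
                      transform = t$transform_tag, source_id = t$source_id)
  }
  jsonlite::write_json(list(seed = tileset$seed, tiles = rows),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a tile store written by [write_tileset()]
#' @param dir tile store directory.
#' @return a `wn_tileset`.
#' @export
read_tileset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  tiles <- vector("list", length(man$tiles))
  labs <- character(length(man$tiles))
  for (i in seq_along(man$tiles)) {
    r <- man$tiles[[i]]
    tiles[[i]] <- new_tile(read_raster(file.path(dir, r$image)),
                           binarize_mask(tiff::readTIFF(file.path(dir, r$mask))),
                           origin = unlist(r$origin),
                           transform_tag = r$transform,
                           source_id = r$source_id)
    labs[i] <- r$split
  }
  new_tileset(tiles,
              split_labels = if (all(labs == "all")) NULL else labs,
              seed = if (is.null(man$seed)) NA_integer_ else man$seed)
}
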