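# Open-format persistence: multichannel TIFF + JSON sidecar for images,
# CSV/JSON/TIFF for every intermediate, so any stage can be audited or
# rerun in isolation.

#' Write / read a calibrated multichannel TIFF
#'
#' Channels are stored as 16-bit TIFF directories; channel names, pixel
#' size, intensity scaling, and image metadata go to a JSON sidecar
#' (`<path>.json`) so the file pair round-trips through
#' `read_multichannel_tiff()`.
#'
#' @param image a `multichannel_image`.
#' @param path output TIFF path.
#' @return `write_multichannel_tiff()` returns `path` invisibly;
#'   `read_multichannel_tiff()` returns a `multichannel_image`.
#' @export
write_multichannel_tiff <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  lo <- min(vapply(image$channels, min, 0))
  hi <- max(vapply(image$channels, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  norm <- lapply(image$channels, function(ch) (ch - lo) / scale)
  tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channels = names(image$channels), pixel_size = image$pixel_size,
         intensity_min = lo, intensity_scale = scale, meta = image$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_multichannel_tiff
#' @export
read_multichannel_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  channels <- lapply(slices, function(m) {
    m * side$intensity_scale + side$intensity_min
  })
  names(channels) <- side$channels
  new_multichannel_image(channels, side$pixel_size,
                         meta = as.list(side$meta))
}

#' Persist / restore an epithelial boundary
#'
#' Writes `<prefix>_coords.csv` (ordered row/col chain),
#' `<prefix>_mask.tif` (tissue mask), and `<prefix>.json` (provenance,
#' pixel size, luminal side).
#'
#' @param boundary an `epithelial_boundary`.
#' @param prefix file path prefix.
#' @return `write_boundary()` returns `prefix` invisibly; `read_boundary()`
#'   returns an `epithelial_boundary`.
#' @export
write_boundary <- function(boundary, prefix) {
  stopifnot(inherits(boundary, "epithelial_boundary"))
  utils::write.csv(as.data.frame(boundary$coords),
                   paste0(prefix, "_coords.csv"), row.names = FALSE)
  tiff::writeTIFF(boundary$tissue_mask * 1, paste0(prefix, "_mask.tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(
    list(provenance = boundary$provenance, pixel_size = boundary$pixel_size,
         luminal_side = boundary$luminal_side),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_boundary
#' @export
read_boundary <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  coords <- as.matrix(utils::read.csv(paste0(prefix, "_coords.csv")))
  mask <- tiff::readTIFF(paste0(prefix, "_mask.tif")) > 0.5
  new_epithelial_boundary(mask, coords, provenance = side$provenance,
                          pixel_size = side$pixel_size,
                          luminal_side = side$luminal_side)
}

#' Persist a debris mask and its object table
#' @param dm a `debris_mask`.
#' @param prefix file path prefix (writes `<prefix>_mask.tif` and
#'   `<prefix>_objects.csv`).
#' @return `prefix`, invisibly.
#' @export
write_debris <- function(dm, prefix) {
  stopifnot(inherits(dm, "debris_mask"))
  tiff::writeTIFF(dm$mask * 1, paste0(prefix, "_mask.tif"),
                  bits.per.sample = 8L)
  utils::write.csv(dm$table, paste0(prefix, "_objects.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
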