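#' Parameters for debris identification
#'
#' @param broadband_ratio minimum cross-channel intensity ratio (second
#'   brightest / brightest, after per-channel threshold normalization) for
#'   an object to be called broadband autofluorescence; in (0, 1].
#' @param size_max_bacterium_um2 objects larger than this are debris
#'   candidates (single bacteria are a few square micrometers).
#' @param min_object_area_um2 components smaller than this are discarded as
#'   noise during segmentation.
#' @return object of class `debris_params`.
#' @export
debris_params <- function(broadband_ratio = 0.5,
                          size_max_bacterium_um2 = 20,
                          min_object_area_um2 = 0.5) {
  if (broadband_ratio <= 0 || broadband_ratio > 1) {
    stop_field("broadband_ratio", "must be in (0, 1]")
  }
  if (!(size_max_bacterium_um2 > min_object_area_um2) ||
        min_object_area_um2 <= 0) {
    stop_field("size_max_bacterium_um2",
               "must exceed min_object_area_um2 > 0")
  }
  structure(list(broadband_ratio = broadband_ratio,
                 size_max_bacterium_um2 = size_max_bacterium_um2,
                 min_object_area_um2 = min_object_area_um2),
            class = "debris_params")
}

#' Segment luminal objects across channels
#'
#' Connected components of supra-threshold signal on the luminal side of
#' the boundary.  Each channel is thresholded independently (Otsu over the
#' luminal pixels); the union of supra-threshold pixels is labelled with
#' 8-connectivity and components below the minimum area are discarded.
#' Objects merged by blur into one component stay one label (no
#' splitting).
#'
#' @param channels named list of channel matrices (include the channels in
#'   which objects are visible, e.g. FISH probes and DAPI; diffuse mucus
#'   staining is normally left out so that the mucus cloud is not
#'   segmented as one giant object).
#' @param tissue_mask logical matrix, `TRUE` = tissue.
#' @param params a [debris_params()].
#' @param pixel_size micrometers per pixel.
#' @return list of class `luminal_objects`: `labels` (integer matrix, 0 =
#'   background), `table` (label, area_um2, centroid_row, centroid_col),
#'   `thresholds` (per input channel), `pixel_size`.
#' @export
segment_luminal_objects <- function(channels, tissue_mask,
                                    params = debris_params(),
                                    pixel_size = 1) {
  stopifnot(is.list(channels), length(channels) >= 1)
  lumen <- !tissue_mask
  if (!any(lumen)) stop("no luminal pixels", call. = FALSE)
  for (nm in names(channels)) {
    check_same_shape(channels[[nm]], tissue_mask, nm, "tissue_mask")
  }
  thresholds <- vapply(channels, function(ch) {
    otsu_threshold(ch, mask = lumen)
  }, 0)
  supra <- matrix(FALSE, nrow(tissue_mask), ncol(tissue_mask))
  for (nm in names(channels)) {
    if (is.na(thresholds[[nm]])) next
    supra <- supra | (channels[[nm]] >= thresholds[[nm]])
  }
  supra <- supra & lumen
  lab <- as_mat(EBImage::bwlabel(supra))
  n_obj <- max(lab)
  if (n_obj > 0) {
    areas <- tabulate(lab[lab > 0], n_obj) * pixel_size^2
    keep <- which(areas >= params$min_object_area_um2)
    remap <- integer(n_obj)
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
    n_obj <- length(keep)
  }
  tab <- if (n_obj > 0) {
    idx <- which(lab > 0)
    l <- lab[idx]
    rr <- (idx - 1) %% nrow(lab) + 1
    cc <- (idx - 1) %/% nrow(lab) + 1
    data.frame(label = seq_len(n_obj),
               area_um2 = tabulate(l, n_obj) * pixel_size^2,
               centroid_row = as.vector(tapply(rr, l, mean)),
               centroid_col = as.vector(tapply(cc, l, mean)))
  } else {
    data.frame(label = integer(), area_um2 = numeric(),
               centroid_row = numeric(), centroid_col = numeric())
  }
  structure(list(labels = lab, table = tab, thresholds = thresholds,
                 pixel_size = pixel_size),
            class = "luminal_objects")
}

#' Classify luminal objects as debris or microbial signal
#'
#' Realizes debris subtraction for autofluorescent objects (plant
#' material, shed epithelial cells) with three auditable rules.  An object
#' is debris iff at least one holds:
#' \describe{
#'   \item{broadband}{supra-threshold mean intensity in >= 2 channels with
#'     a cross-channel (second-brightest / brightest, threshold-normalized)
#'     ratio of at least `broadband_ratio` - true fluorophores are
#'     spectrally confined, autofluorescence is not;}
#'   \item{oversize}{area above `size_max_bacterium_um2`;}
#'   \item{dapi_fragment}{DAPI-positive object detached from the tissue
#'     (a shed host-cell fragment; bacterial FISH puncta are DAPI-dim).}
#' }
#' Every retained (non-debris) object is treated as microbial signal.
#'
#' @param objects a `luminal_objects` from [segment_luminal_objects()].
#' @param channels named list of ALL channel matrices, which must include
#'   `DAPI` (the detached-fragment rule is undecidable without it).
#' @param params a [debris_params()].
#' @return list of class `debris_mask`: `mask` (logical matrix), `table`
#'   (per object: label, area_um2, per-channel mean intensity, debris flag,
#'   reason).
#' @export
classify_debris <- function(objects, channels, params = debris_params()) {
  stopifnot(inherits(objects, "luminal_objects"))
  if (!"DAPI" %in% names(channels)) {
    stop("channel set lacks DAPI: detached-fragment rule is undecidable",
         call. = FALSE)
  }
  lab <- objects$labels
  tab <- objects$table
  n_obj <- nrow(tab)
  ch_means <- matrix(0, n_obj, length(channels),
                     dimnames = list(NULL, names(channels)))
  # Per-channel positivity thresholds: reuse the segmentation thresholds,
  # deriving one from the off-object pixels for channels that were not
  # part of segmentation (e.g. a diffuse mucus channel).
  ch_thr <- vapply(names(channels), function(nm) {
    th <- if (nm %in% names(objects$thresholds)) {
      objects$thresholds[[nm]]
    } else {
      otsu_threshold(channels[[nm]], mask = lab == 0)
    }
    if (is.na(th)) Inf else th
  }, 0)
  if (n_obj > 0) {
    idx <- which(lab > 0)
    l <- lab[idx]
    for (nm in names(channels)) {
      ch_means[, nm] <- as.vector(tapply(channels[[nm]][idx], l, mean))
    }
  }
  debris <- logical(n_obj)
  reason <- character(n_obj)
  for (i in seq_len(n_obj)) {
    norm <- ch_means[i, ] / ch_thr
    pos <- norm >= 1
    srt <- sort(norm, decreasing = TRUE)
    reasons <- character()
    if (sum(pos) >= 2 && srt[2] / srt[1] >= params$broadband_ratio) {
      reasons <- c(reasons, "broadband")
    }
    if (tab$area_um2[i] > params$size_max_bacterium_um2) {
      reasons <- c(reasons, "oversize")
    }
    if (isTRUE(pos[["DAPI"]])) {
      reasons <- c(reasons, "dapi_fragment")
    }
    debris[i] <- length(reasons) > 0
    reason[i] <- paste(reasons, collapse = "+")
  }
  mask <- matrix(FALSE, nrow(lab), ncol(lab))
  if (any(debris)) {
    mask[lab %in% tab$label[debris]] <- TRUE
  }
  out_tab <- cbind(tab, as.data.frame(ch_means),
                   debris = debris, reason = reason)
  structure(list(mask = mask, table = out_tab,
                 pixel_size = objects$pixel_size),
            class = "debris_mask")
}

#' @export
print.debris_mask <- function(x, ...) {
  cat(sprintf("<debris_mask> %d/%d objects flagged (%.3g%% of frame)\n",
              sum(x$table$debris), nrow(x$table), 100 * mean(x$mask)))
  invisible(x)
}

#' Subtract debris from a channel
#'
#' Pixels under the debris mask are replaced by the background estimate
#' (default 0); all other pixels are untouched, so the operation conserves
#' off-mask signal exactly and is idempotent.  Binned profile means use
#' pixel counts that exclude masked pixels, so the replacement value never
#' biases a bin (pass the mask as `exclude_mask` to [bin_profile()]).
#'
#' @param channel 2-D numeric matrix.
#' @param mask a `debris_mask` or logical matrix of the same shape.
#' @param background replacement value.
#' @return the cleaned channel matrix.
#' @export
subtract_debris <- function(channel, mask, background = 0) {
  m <- if (inherits(mask, "debris_mask")) mask$mask else mask
  check_same_shape(channel, m, "channel", "mask")
  channel[m] <- background
  channel
}
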