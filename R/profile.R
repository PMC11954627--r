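#' Signed Euclidean distance field to the epithelial boundary
#'
#' Computes, for every pixel, the exact Euclidean distance (in micrometers,
#' between pixel centers) to the nearest boundary pixel, signed negative
#' inside tissue and positive on the luminal side.  Boundary pixels have
#' distance 0.
#'
#' @param boundary an `epithelial_boundary` (from [detect_boundary()],
#'   [manual_boundary()], or generator ground truth).
#' @param image_shape integer `(rows, cols)`; defaults to the tissue-mask
#'   shape.
#' @param pixel_size micrometers per pixel.
#' @return a numeric matrix of class `distance_field` with attribute
#'   `pixel_size`.
#' @examples
#' tm <- matrix(FALSE, 8, 8); tm[, 1] <- TRUE
#' b <- mucoprofiler:::new_epithelial_boundary(
#'   tm, cbind(row = 1:8, col = rep(1L, 8)), pixel_size = 1)
#' compute_distance_field(b, c(8, 8), 1)[1, ]  # 0, 1, 2, ...
#' @export
compute_distance_field <- function(boundary,
                                   image_shape = dim(boundary$tissue_mask),
                                   pixel_size = boundary$pixel_size) {
  stopifnot(inherits(boundary, "epithelial_boundary"))
  if (is.null(boundary$coords) || nrow(boundary$coords) == 0) {
    stop("empty boundary", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || is.na(pixel_size) || pixel_size <= 0) {
    stop_field("pixel_size", "must be > 0")
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  seed_img <- matrix(1, nr, nc)
  seed_img[boundary$coords] <- 0
  d <- as_mat(EBImage::distmap(seed_img, metric = "euclidean")) * pixel_size
  sgn <- matrix(1, nr, nc)
  sgn[boundary$tissue_mask] <- -1
  sgn[boundary$coords] <- 1   # boundary pixels carry distance 0
  structure(d * sgn, class = "distance_field", pixel_size = pixel_size)
}

new_density_profile <- function(bin_edges, mean, n_pixels, channel,
                                normalized = FALSE, meta = list()) {
  structure(list(bin_edges = bin_edges, mean = mean, n_pixels = n_pixels,
                 channel = channel, normalized = normalized, meta = meta),
            class = "density_profile")
}

#' Bin centers of a density profile
#' @param profile a `density_profile`.
#' @return numeric vector of bin-center distances, micrometers.
#' @export
bin_centers <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Distance-binned density profile of a channel
#'
#' Averages the channel intensity along the epithelium into uniform
#' half-open distance bins `[lo, hi)`: bin k's value is the mean intensity
#' over all pixels whose signed boundary distance falls in that bin and
#' that are not excluded.  Tissue-side signal (negative distances) is
#' outside the default range; bins that receive no pixels are recorded as
#' `NA` with a pixel count of 0, never as silent zeros.
#'
#' @param channel 2-D numeric matrix.
#' @param field a `distance_field` of the same shape.
#' @param bin_width bin width, micrometers, > 0.
#' @param range length-2 numeric, the half-open profiling range `[lo, hi)`
#'   in micrometers; `hi` must exceed 0 (the range cannot lie entirely
#'   inside tissue) and must be an integer number of bins above `lo`.
#' @param exclude_mask optional logical matrix; `TRUE` pixels (e.g. debris)
#'   are left out of every bin.
#' @param channel_name label stored in the profile.
#' @param meta named list of identifiers (image, animal, group).
#' @return a `density_profile`: `bin_edges`, `mean`, `n_pixels`,
#'   `channel`, `normalized = FALSE`, `meta`.
#' @export
bin_profile <- function(channel, field, bin_width = 1, range = c(0, 100),
                        exclude_mask = NULL, channel_name = "signal",
                        meta = list()) {
  check_matrix2d(channel, "channel")
  check_same_shape(channel, field, "channel", "field")
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_field("bin_width", "must be > 0")
  }
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) stop_field("range", "must satisfy hi > lo")
  if (hi <= 0) {
    stop("profiling range lies entirely inside tissue (hi <= 0)",
         call. = FALSE)
  }
  nb <- (hi - lo) / bin_width
  if (abs(nb - round(nb)) > 1e-8) {
    stop_field("range", "must span an integer number of bins")
  }
  nb <- as.integer(round(nb))
  d <- as.vector(unclass(field))
  v <- as.vector(channel)
  keep <- d >= lo & d < hi
  if (!is.null(exclude_mask)) {
    check_same_shape(channel, exclude_mask, "channel", "exclude_mask")
    keep <- keep & !as.vector(exclude_mask)
  }
  idx <- floor((d[keep] - lo) / bin_width) + 1
  counts <- tabulate(idx, nb)
  if (!any(counts > 0)) stop("all bins are empty", call. = FALSE)
  sums <- numeric(nb)
  agg <- rowsum(v[keep], idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  new_density_profile(bin_edges = lo + bin_width * (0:nb), mean = means,
                      n_pixels = counts, channel = channel_name,
                      meta = meta)
}

#' Z-normalize a density profile
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (denominator n - 1) of the non-missing bin means, the normalization the
#' profiling method applies to every per-image profile before group
#' comparison.  Pixel counts are preserved.
#'
#' @param profile a `density_profile` with >= 2 non-missing bins and
#'   non-zero spread.
#' @return the normalized profile (`normalized = TRUE`).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  ok <- !is.na(profile$mean)
  if (sum(ok) < 2) {
    stop("cannot normalize a profile with fewer than 2 non-missing bins",
         call. = FALSE)
  }
  s <- stats::sd(profile$mean[ok])
  if (s < .Machine$double.eps) {
    stop("cannot normalize a constant profile (SD = 0)", call. = FALSE)
  }
  profile$mean <- (profile$mean - mean(profile$mean[ok])) / s
  profile$normalized <- TRUE
  profile
}

#' Extract a sub-window of a profile
#'
#' Returns the bins of `[lo, hi)`; the window must align with existing bin
#' edges.  The default 0-20 um window targets the mucus layer immediately
#' adjacent to the epithelium.
#'
#' @param profile a `density_profile`.
#' @param lo,hi window bounds, micrometers.
#' @return a `density_profile` restricted to the window.
#' @export
extract_window <- function(profile, lo = 0, hi = 20) {
  stopifnot(inherits(profile, "density_profile"))
  e <- profile$bin_edges
  i_lo <- which(abs(e - lo) < 1e-9)
  i_hi <- which(abs(e - hi) < 1e-9)
  if (!length(i_lo) || !length(i_hi) || i_hi <= i_lo) {
    stop("window is not aligned to bin edges or is empty", call. = FALSE)
  }
  bins <- i_lo:(i_hi - 1)
  new_density_profile(bin_edges = e[i_lo:i_hi], mean = profile$mean[bins],
                      n_pixels = profile$n_pixels[bins],
                      channel = profile$channel,
                      normalized = profile$normalized, meta = profile$meta)
}

#' Locate the profile maximum
#'
#' Argmax over non-missing bin means; ties are broken toward the smaller
#' distance.  For a mucus profile this is the distance of maximal mucus
#' density from the epithelial border.
#'
#' @param profile a `density_profile` with >= 1 non-missing bin.
#' @return list with `peak_distance` (bin center, micrometers) and
#'   `peak_value`.
#' @export
find_peak <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  if (all(is.na(profile$mean))) {
    stop("all profile bins are missing", call. = FALSE)
  }
  i <- which.max(profile$mean)   # NA ignored; first max = smaller distance
  list(peak_distance = bin_centers(profile)[i],
       peak_value = profile$mean[i])
}

#' @export
as.data.frame.density_profile <- function(x, ...) {
  data.frame(image = x$meta$image %||% NA_character_,
             animal = x$meta$animal %||% NA_character_,
             group = x$meta$group %||% NA_character_,
             channel = x$channel,
             bin_lo_um = x$bin_edges[-length(x$bin_edges)],
             bin_hi_um = x$bin_edges[-1],
             mean = x$mean, n_pixels = x$n_pixels,
             normalized = x$normalized)
}

#' Combine density profiles into one tidy table
#' @param profiles list of `density_profile` objects.
#' @return data.frame with one row per profile bin (columns image, animal,
#'   group, channel, bin_lo_um, bin_hi_um, mean, n_pixels, normalized).
#' @export
profiles_table <- function(profiles) {
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, as.data.frame))
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %s: %d bins of %.3g um over [%.3g, %.3g) um%s\n",
              x$channel, length(x$mean), diff(x$bin_edges[1:2]),
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              if (x$normalized) ", z-normalized" else ""))
  if (length(x$meta)) {
    cat("  ", paste(names(x$meta), unlist(x$meta), sep = "=",
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(bin_centers(x), x$mean, type = "l",
                 xlab = "distance from epithelium (um)",
                 ylab = if (x$normalized) "normalized density" else
                   "mean intensity",
                 main = x$channel, ...)
  invisible(x)
}

#' Average per-image profiles into per-animal profiles
#'
#' The animal is the experimental unit of the group comparison: profiles
#' from multiple images of one animal are averaged bin-wise (missing bins
#' propagate) into a single profile per animal.
#'
#' @param profiles tidy profile table from [profiles_table()] (or a list of
#'   `density_profile` objects).  Every row must carry `animal` and `group`
#'   labels and share one bin grid.
#' @return data.frame: animal, group, bin_lo_um, bin_hi_um, mean,
#'   n_images.
#' @export
aggregate_by_animal <- function(profiles) {
  df <- if (is.data.frame(profiles)) profiles else profiles_table(profiles)
  if (any(is.na(df$animal)) || any(is.na(df$group))) {
    stop("every profile must carry animal and group labels", call. = FALSE)
  }
  grids <- unique(df[, c("bin_lo_um", "bin_hi_um")])
  per_image <- split(df$bin_lo_um, df$image)
  n_bins <- vapply(per_image, length, 0L)
  if (length(unique(n_bins)) != 1 ||
        nrow(grids) != unname(n_bins[1])) {
    stop("profiles use mixed bin grids", call. = FALSE)
  }
  agg <- stats::aggregate(mean ~ animal + group + bin_lo_um + bin_hi_um,
                          data = df, FUN = mean, na.action = stats::na.pass)
  n_img <- stats::aggregate(list(n_images = df$image),
                            by = list(animal = df$animal),
                            FUN = function(x) length(unique(x)))
  out <- merge(agg, n_img, by = "animal")
  out[order(out$group, out$animal, out$bin_lo_um), , drop = FALSE]
}
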