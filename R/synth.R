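#' Generate one synthetic multichannel intestinal-section scene
#'
#' Renders a calibrated multichannel fluorescence image with full ground
#' truth.  The scene contains (i) a tissue band of dense nuclei below a
#' sinusoidal lumen-facing epithelial boundary (the DAPI channel), (ii) one
#' rendered channel per [channel_model()] whose expected intensity or
#' point-process rate is a known function of signed distance from the true
#' boundary, (iii) broadband autofluorescent debris objects rendered into
#' every channel, (iv) a spatially correlated luminal background texture on
#' diffuse channels, and (v) mixed Poisson-Gaussian noise.  Identical
#' configurations (including seed) yield bit-identical scenes.
#'
#' @param config a [scene_config()].
#' @return a list of class `muco_scene` with elements
#'   \describe{
#'     \item{image}{`multichannel_image`: named list of channel matrices
#'       (always including `DAPI`), `pixel_size`, `meta`.}
#'     \item{truth}{`scene_truth`: `boundary_coords` (ordered row/col pixel
#'       chain on the edge of the true tissue mask), `tissue_mask`,
#'       `distance_um` (true signed distance field), `intensity_fns`,
#'       `debris_mask`, `debris_table`, `centroids` (per punctate channel),
#'       and `clean_channels` (expected noise-free, debris-free channels).}
#'   }
#' @examples
#' sc <- generate_scene(ileum_scene_config(image_shape = c(96, 96), seed = 7))
#' names(sc$image$channels)
#' @export
generate_scene <- function(config) {
  config <- validate_scene_config(config)
  with_seed(config$seed, render_scene(config))
}

render_scene <- function(config) {
  nr <- config$image_shape[1]
  nc <- config$image_shape[2]
  ps <- config$pixel_size
  b <- config$boundary

  # True boundary curve: y (um, from top) as a function of x (um).
  x_um <- (seq_len(nc) - 0.5) * ps
  y_b <- b$baseline_um +
    b$amplitude_um * sin(2 * pi * x_um / b$period_um + b$phase)
  y_px <- (seq_len(nr) - 0.5) * ps
  tissue_mask <- outer(y_px, y_b, `>`)

  boundary_coords <- order_chain(which(edge_of_mask(tissue_mask) &
                                         tissue_mask, arr.ind = TRUE))
  colnames(boundary_coords) <- c("row", "col")
  truth_boundary <- new_epithelial_boundary(tissue_mask, boundary_coords,
                                            provenance = "truth",
                                            pixel_size = ps)
  dfield <- compute_distance_field(truth_boundary, c(nr, nc), ps)
  d <- unclass(dfield)

  # DAPI: diffuse cytoplasmic level plus nuclei disks inside tissue.
  nu <- config$nuclei
  dapi <- config$nuclei$tissue_intensity * tissue_mask
  tissue_idx <- which(tissue_mask)
  area_um2 <- length(tissue_idx) * ps^2
  n_nuc <- stats::rpois(1, nu$density * area_um2)
  if (n_nuc > 0 && length(tissue_idx)) {
    pick <- sample(tissue_idx, n_nuc, replace = TRUE)
    rr <- (pick - 1) %% nr + 1 + stats::runif(n_nuc, -0.5, 0.5)
    cc <- (pick - 1) %/% nr + 1 + stats::runif(n_nuc, -0.5, 0.5)
    rad <- stats::runif(n_nuc, nu$radius_um[1], nu$radius_um[2]) / ps
    val <- stats::runif(n_nuc, nu$intensity[1], nu$intensity[2])
    dapi <- paint_disks_max(dapi, rr, cc, rad, val)
    dapi[!tissue_mask] <- 0   # nuclei are confined to the tissue
  }

  # Debris: broadband luminal disks, fully inside the lumen and disjoint
  # from bacterial puncta (puncta rates are zeroed under debris).
  de <- config$debris
  debris_mask <- matrix(FALSE, nr, nc)
  debris_rows <- list()
  if (de$count > 0) {
    lum_idx <- which(d > de$radius_um[2] + 1)
    for (i in seq_len(de$count)) {
      if (!length(lum_idx)) break
      pick <- sample(lum_idx, 1)
      r0 <- (pick - 1) %% nr + 1
      c0 <- (pick - 1) %/% nr + 1
      rad_um <- stats::runif(1, de$radius_um[1], de$radius_um[2])
      base <- de$intensity * stats::runif(1, 0.8, 1.2)
      disk <- matrix(FALSE, nr, nc)
      disk <- paint_disk_max(disk * 0, r0, c0, rad_um / ps, 1) > 0
      debris_mask <- debris_mask | disk
      debris_rows[[i]] <- data.frame(
        id = i, row = r0, col = c0, radius_um = rad_um,
        area_um2 = sum(disk) * ps^2, base_intensity = base)
    }
  }
  debris_table <- if (length(debris_rows)) {
    do.call(rbind, debris_rows)
  } else {
    data.frame(id = integer(), row = integer(), col = integer(),
               radius_um = numeric(), area_um2 = numeric(),
               base_intensity = numeric())
  }

  # Per-channel broadband debris intensity (correlated across channels).
  channel_names <- c("DAPI", vapply(config$channels, `[[`, "", "name"))
  debris_maps <- stats::setNames(vector("list", length(channel_names)),
                                 channel_names)
  for (nm in channel_names) debris_maps[[nm]] <- matrix(0, nr, nc)
  if (nrow(debris_table)) {
    for (i in seq_len(nrow(debris_table))) {
      ob <- debris_table[i, ]
      for (nm in channel_names) {
        lvl <- ob$base_intensity * stats::runif(1, 0.85, 1)
        debris_maps[[nm]] <- paint_disk_max(debris_maps[[nm]], ob$row,
                                            ob$col, ob$radius_um / ps, lvl)
      }
    }
  }

  # Signal channels.
  bgc <- config$background
  lum <- d > 0
  channels <- list(DAPI = dapi)
  clean_channels <- list(DAPI = dapi)
  centroids <- list()
  intensity_fns <- list()
  for (ch in config$channels) {
    fn <- ch$intensity_fn
    intensity_fns[[ch$name]] <- fn
    if (ch$kind == "diffuse") {
      clean <- ch$amplitude * matrix(fn(as.vector(d)), nr, nc)
      if (bgc$sd > 0 || bgc$offset > 0) {
        bg <- (bgc$offset + bgc$sd * random_field(nr, nc, bgc$corr_um, ps)) *
          lum
        clean <- clean + bg
      }
    } else {
      rate_px <- ch$amplitude * matrix(fn(as.vector(d)), nr, nc) * ps^2
      rate_px[debris_mask] <- 0
      counts <- matrix(stats::rpois(nr * nc, rate_px), nr, nc)
      hit <- which(counts > 0)
      if (length(hit)) {
        centroids[[ch$name]] <- data.frame(
          row = rep((hit - 1) %% nr + 1, counts[hit]),
          col = rep((hit - 1) %/% nr + 1, counts[hit]))
      } else {
        centroids[[ch$name]] <- data.frame(row = integer(), col = integer())
      }
      sig_px <- ch$puncta_sigma / ps
      half <- max(1L, ceiling(3 * sig_px))
      ax <- (-half):half
      kern <- exp(-outer(ax^2, ax^2, `+`) / (2 * sig_px^2))
      clean <- as_mat(EBImage::filter2(counts * ch$puncta_intensity, kern,
                                       boundary = "replicate"))
    }
    clean[clean < 0] <- 0
    clean_channels[[ch$name]] <- clean
    channels[[ch$name]] <- pmax(clean, debris_maps[[ch$name]])
  }
  channels$DAPI <- pmax(channels$DAPI, debris_maps$DAPI)

  # Detection noise: Poisson shot noise on expected intensity + Gaussian
  # read noise.  Values are not clamped at zero (offset-subtracted data).
  no <- config$noise
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (no$poisson_scale > 0) {
      v <- matrix(stats::rpois(nr * nc, pmax(v, 0) * no$poisson_scale) /
                    no$poisson_scale, nr, nc)
    }
    if (no$gaussian_sd > 0) {
      v <- v + matrix(stats::rnorm(nr * nc, 0, no$gaussian_sd), nr, nc)
    }
    channels[[nm]] <- v
  }

  image <- new_multichannel_image(channels, ps, meta = list())
  truth <- structure(list(boundary_coords = boundary_coords,
                          tissue_mask = tissue_mask,
                          distance_um = dfield,
                          intensity_fns = intensity_fns,
                          debris_mask = debris_mask,
                          debris_table = debris_table,
                          centroids = centroids,
                          clean_channels = clean_channels,
                          config = config),
                     class = "scene_truth")
  structure(list(image = image, truth = truth), class = "muco_scene")
}

new_multichannel_image <- function(channels, pixel_size, meta = list()) {
  structure(list(channels = channels, pixel_size = pixel_size, meta = meta),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_image> %dx%d px @ %.3g um/px; channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.muco_scene <- function(x, ...) {
  print(x$image)
  cat(sprintf("  truth: %d boundary px, %d debris objects, seed %d\n",
              nrow(x$truth$boundary_coords), nrow(x$truth$debris_table),
              x$truth$config$seed))
  invisible(x)
}

#' Generate a labelled two-group synthetic experiment
#'
#' Builds `2 * n_per_group` scenes (one per animal) in two groups, where
#' group B channel amplitudes are `effect` times those of group A for every
#' non-DAPI channel (or the subset in `scale_channels`).  This mirrors a
#' genotype comparison in which the mutant's mucus or bacterial signal is a
#' constant multiple of wild type; the default study-scale effect ratio of
#' 3 reflects the roughly three-fold mucus-density difference the method is
#' designed to resolve.  Per-animal biological variability is drawn first
#' (lognormal amplitude factors with CV `animal_cv`; Gaussian-profile
#' center jitter with SD `center_jitter_um`), then per-animal scene seeds
#' are derived deterministically from `seed`, so the full experiment is
#' reproducible from the master seed alone.
#'
#' @param config_base a [scene_config()] shared by both groups.
#' @param n_per_group animals per group, >= 1.
#' @param effect group B / group A amplitude ratio, > 0 (1 = null
#'   experiment).
#' @param seed master seed.
#' @param scale_channels channel names to scale (default: all non-DAPI).
#' @param group_names length-2 character vector of group labels.
#' @return object of class `scene_experiment`: list with `scenes` (list of
#'   `muco_scene`), `meta` (data.frame: image, animal, group, seed), and
#'   the generating parameters.
#' @export
make_group_experiment <- function(config_base, n_per_group, effect = 3,
                                  seed = 1L,
                                  scale_channels = NULL,
                                  group_names = c("A", "B")) {
  stopifnot(inherits(config_base, "scene_config"))
  if (!is.numeric(n_per_group) || n_per_group < 1) {
    stop("n_per_group must be >= 1", call. = FALSE)
  }
  if (!is.numeric(effect) || effect <= 0) {
    stop("effect must be > 0", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group)
  ch_names <- vapply(config_base$channels, `[[`, "", "name")
  scale_channels <- scale_channels %||% ch_names
  n_tot <- 2L * n_per_group

  animal_pars <- with_seed(seed, {
    lapply(seq_len(n_tot), function(i) {
      list(amp_factor = stats::setNames(
             exp(stats::rnorm(length(ch_names), 0,
                              config_base$animal_cv)), ch_names),
           center_shift = stats::setNames(
             stats::rnorm(length(ch_names), 0,
                          config_base$center_jitter_um), ch_names))
    })
  })

  scenes <- vector("list", n_tot)
  meta <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    grp_idx <- if (i <= n_per_group) 1L else 2L
    grp <- group_names[grp_idx]
    animal <- sprintf("%s%d", grp, if (grp_idx == 1L) i else i - n_per_group)
    cfg <- config_base
    cfg$seed <- derive_seed(seed, i)
    cfg$channels <- lapply(config_base$channels, function(ch) {
      amp <- ch$amplitude * animal_pars[[i]]$amp_factor[[ch$name]]
      if (grp_idx == 2L && ch$name %in% scale_channels) {
        amp <- amp * effect
      }
      sp <- attr(ch$intensity_fn, "spec")
      fn <- ch$intensity_fn
      if (identical(sp$form, "gaussian") && config_base$center_jitter_um > 0) {
        fn <- intensity_gaussian(
          max(sp$center + animal_pars[[i]]$center_shift[[ch$name]], 0.5),
          sp$sd)
      }
      channel_model(ch$name, ch$kind, fn, amp, ch$puncta_intensity,
                    ch$puncta_sigma)
    })
    sc <- generate_scene(cfg)
    sc$image$meta <- list(image = sprintf("%s_img1", animal),
                          animal = animal, group = grp)
    scenes[[i]] <- sc
    meta[[i]] <- data.frame(image = sc$image$meta$image, animal = animal,
                            group = grp, seed = cfg$seed)
  }
  structure(list(scenes = scenes, meta = do.call(rbind, meta),
                 effect = effect, n_per_group = n_per_group,
                 seed = as.integer(seed), group_names = group_names,
                 config_base = config_base),
            class = "scene_experiment")
}

#' @export
print.scene_experiment <- function(x, ...) {
  cat(sprintf("<scene_experiment> %d scenes (%d per group), effect ratio %.3g, seed %d\n",
              length(x$scenes), x$n_per_group, x$effect, x$seed))
  print(x$meta, row.names = FALSE)
  invisible(x)
}
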