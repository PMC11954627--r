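#' Configure a full profiling run
#'
#' One validated object drives the whole pipeline: scene simulation (or
#' image loading), boundary detection, debris subtraction, profiling, and
#' group statistics.
#'
#' @param experiment either a [make_group_experiment()] result, or a list
#'   `list(config = <scene_config>, n_per_group =, effect =)` describing
#'   the synthetic experiment to generate; mutually exclusive with
#'   `images`.
#' @param images list of `multichannel_image` objects or character paths to
#'   TIFFs written by [write_multichannel_tiff()]; each image's `meta` must
#'   carry `image`, `animal`, and `group`.
#' @param dapi_channel name of the DAPI channel (must exist in the channel
#'   map).
#' @param profile_channels channels to profile; default: all non-DAPI.
#' @param object_channels channels used for object segmentation; default:
#'   the punctate channels plus DAPI for synthetic experiments, and all
#'   channels for file input (name them explicitly to keep a diffuse
#'   mucus channel out of segmentation).
#' @param boundary_params a [boundary_params()].
#' @param debris debris handling: `TRUE` (default) to classify and subtract
#'   debris, `FALSE` to skip.
#' @param debris_params a [debris_params()].
#' @param boundary_source `"detect"` (run [detect_boundary()]) or
#'   `"truth"` (use generator ground truth; synthetic experiments only).
#' @param bin_width_um,range_um,window_um,at_um profiling geometry: bin
#'   width, full profiling range, ANOVA window, pointwise comparison
#'   distances (bin centers).
#' @param normalize z-normalize each per-image profile over the full range
#'   before aggregation (the method's standard transform).
#' @param n_perm permutations for the animal-level group test.
#' @param seed master seed for the synthetic experiment.
#' @param out_dir directory for persisted artifacts, or NULL to keep the
#'   run in memory.
#' @return validated object of class `run_config`.
#' @export
run_config <- function(experiment = NULL, images = NULL,
                       dapi_channel = "DAPI",
                       profile_channels = NULL,
                       object_channels = NULL,
                       boundary_params = mucoprofiler::boundary_params(),
                       debris = TRUE,
                       debris_params = mucoprofiler::debris_params(),
                       boundary_source = c("detect", "truth"),
                       bin_width_um = 1, range_um = c(0, 60),
                       window_um = c(0, 20), at_um = c(0.5, 10.5),
                       normalize = TRUE, n_perm = 999,
                       seed = 1L, out_dir = NULL) {
  boundary_source <- match.arg(boundary_source)
  if (is.null(experiment) == is.null(images)) {
    stop("exactly one of 'experiment' or 'images' must be given",
         call. = FALSE)
  }
  if (!is.null(experiment) && !inherits(experiment, "scene_experiment")) {
    need <- c("config", "n_per_group")
    if (!is.list(experiment) || !all(need %in% names(experiment))) {
      stop_field("experiment",
                 "must be a scene_experiment or list(config=, n_per_group=, effect=)")
    }
  }
  if (!is.null(images)) {
    if (is.character(images)) {
      missing_files <- images[!file.exists(images)]
      if (length(missing_files)) {
        stop_field("images", paste("refers to missing files:",
                                   paste(missing_files, collapse = ", ")))
      }
    }
    if (boundary_source == "truth") {
      stop_field("boundary_source",
                 "'truth' is only available for synthetic experiments")
    }
  }
  if (!is.character(dapi_channel) || !nzchar(dapi_channel)) {
    stop_field("dapi_channel", "must name the DAPI channel")
  }
  if (range_um[2] <= range_um[1] || bin_width_um <= 0) {
    stop_field("range_um", "must satisfy hi > lo with bin_width_um > 0")
  }
  structure(list(experiment = experiment, images = images,
                 dapi_channel = dapi_channel,
                 profile_channels = profile_channels,
                 object_channels = object_channels,
                 boundary_params = boundary_params,
                 debris = isTRUE(debris), debris_params = debris_params,
                 boundary_source = boundary_source,
                 bin_width_um = bin_width_um, range_um = range_um,
                 window_um = window_um, at_um = at_um,
                 normalize = isTRUE(normalize), n_perm = n_perm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, image_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed%s: %s", name,
                 if (is.null(image_id)) "" else
                   sprintf(" for image '%s'", image_id),
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full profiling pipeline
#'
#' Executes simulate/load -> boundary -> debris -> profile -> stats from
#' one [run_config()], persisting every intermediate (images, boundaries,
#' debris masks, profiles, reports) under `out_dir` when given.  Outputs
#' are a pure function of the configuration and seed, so a rerun on the
#' same config produces byte-identical CSV/JSON artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir overrides `config$out_dir`.
#' @return object of class `muco_pipeline`: `profiles` (tidy per-image
#'   table), `by_animal` (per channel), `anova`, `permutation`,
#'   `pointwise`, `reports` (per channel `profile_report`), `boundaries`,
#'   `debris`, `config`.
#' @examples
#' \donttest{
#' cfg <- run_config(
#'   experiment = list(config = ileum_scene_config(c(128, 128), seed = 3),
#'                     n_per_group = 3, effect = 3),
#'   range_um = c(0, 40), n_perm = 199)
#' res <- run_pipeline(cfg)
#' res$anova$MUC2$table
#' }
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  # --- stage: simulate / load -------------------------------------------
  if (!is.null(config$experiment)) {
    exper <- stage("simulate", NULL, {
      if (inherits(config$experiment, "scene_experiment")) {
        config$experiment
      } else {
        make_group_experiment(config$experiment$config,
                              config$experiment$n_per_group,
                              effect = config$experiment$effect %||% 1,
                              seed = config$seed)
      }
    })
    scenes <- exper$scenes
    images <- lapply(scenes, `[[`, "image")
    punctate <- vapply(Filter(function(ch) ch$kind == "punctate",
                              exper$config_base$channels),
                       `[[`, "", "name")
    default_objects <- c(punctate, config$dapi_channel)
  } else {
    scenes <- NULL
    images <- stage("load", NULL, {
      if (is.character(config$images)) {
        lapply(config$images, read_multichannel_tiff)
      } else {
        config$images
      }
    })
    default_objects <- NULL
  }
  ids <- vapply(images, function(im) {
    im$meta$image %||% stop("image metadata lacks an 'image' id")
  }, "")
  for (im in images) {
    if (!config$dapi_channel %in% names(im$channels)) {
      stop(sprintf("image '%s' has no channel named '%s'",
                   im$meta$image, config$dapi_channel), call. = FALSE)
    }
  }
  all_channels <- names(images[[1]]$channels)
  profile_channels <- config$profile_channels %||%
    setdiff(all_channels, config$dapi_channel)
  object_channels <- config$object_channels %||% default_objects %||%
    all_channels

  boundaries <- vector("list", length(images))
  debris_masks <- vector("list", length(images))
  profile_rows <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    ps <- im$pixel_size
    dapi <- im$channels[[config$dapi_channel]]

    boundaries[[i]] <- stage("boundary", ids[i], {
      if (config$boundary_source == "truth") {
        tr <- scenes[[i]]$truth
        new_epithelial_boundary(tr$tissue_mask, tr$boundary_coords,
                                provenance = "truth", pixel_size = ps,
                                luminal_side = "oriented")
      } else {
        orient_luminal_side(
          detect_boundary(dapi, config$boundary_params, ps), dapi)
      }
    })

    dmask <- NULL
    if (config$debris) {
      debris_masks[[i]] <- stage("debris", ids[i], {
        objs <- segment_luminal_objects(
          im$channels[intersect(object_channels, names(im$channels))],
          boundaries[[i]]$tissue_mask, config$debris_params, ps)
        classify_debris(objs, im$channels, config$debris_params)
      })
      dmask <- debris_masks[[i]]$mask
    }

    profile_rows[[i]] <- stage("profile", ids[i], {
      field <- compute_distance_field(boundaries[[i]], dim(dapi), ps)
      profs <- lapply(profile_channels, function(nm) {
        ch <- im$channels[[nm]]
        if (!is.null(dmask)) ch <- subtract_debris(ch, dmask)
        p <- bin_profile(ch, field, config$bin_width_um, config$range_um,
                         exclude_mask = dmask, channel_name = nm,
                         meta = im$meta)
        if (config$normalize) p <- normalize_profile(p)
        p
      })
      profiles_table(profs)
    })

    if (!is.null(out_dir)) {
      img_dir <- file.path(out_dir, ids[i])
      dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
      write_multichannel_tiff(im, file.path(img_dir, "image.tif"))
      write_boundary(boundaries[[i]], file.path(img_dir, "boundary"))
      if (!is.null(debris_masks[[i]])) {
        write_debris(debris_masks[[i]], file.path(img_dir, "debris"))
      }
    }
  }
  profiles <- do.call(rbind, profile_rows)
  if (!is.null(out_dir)) {
    utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
  }

  # --- stage: stats ------------------------------------------------------
  by_animal <- list()
  anovas <- list()
  perms <- list()
  pointwise <- list()
  reports <- list()
  for (nm in profile_channels) {
    res <- stage("stats", nm, {
      agg <- aggregate_by_animal(profiles[profiles$channel == nm, ])
      pm <- profile_matrix(agg, window = config$window_um)
      fit <- two_way_anova(pm)
      perm <- permutation_group_test(pm, n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, 777))
      pw <- lapply(config$at_um, function(d) compare_at_distance(pm, d))
      rep <- profile_report(
        agg, fit, permutation = perm, pointwise = pw,
        config = list(seed = config$seed, channel = nm,
                      window_um = config$window_um,
                      bin_width_um = config$bin_width_um,
                      range_um = config$range_um,
                      normalized = config$normalize),
        out_dir = if (is.null(out_dir)) NULL else
          file.path(out_dir, paste0("report_", nm)))
      list(agg = agg, fit = fit, perm = perm, pw = pw, rep = rep)
    })
    by_animal[[nm]] <- res$agg
    anovas[[nm]] <- res$fit
    perms[[nm]] <- res$perm
    pointwise[[nm]] <- res$pw
    reports[[nm]] <- res$rep
  }

  structure(list(profiles = profiles, by_animal = by_animal,
                 anova = anovas, permutation = perms,
                 pointwise = pointwise, reports = reports,
                 boundaries = boundaries, debris = debris_masks,
                 ids = ids, config = config),
            class = "muco_pipeline")
}

#' @export
print.muco_pipeline <- function(x, ...) {
  cat(sprintf("<muco_pipeline> %d images, channels: %s\n", length(x$ids),
              paste(names(x$anova), collapse = ", ")))
  for (nm in names(x$anova)) {
    cat(sprintf("\n== %s (window %g-%g um) ==\n", nm,
                x$config$window_um[1], x$config$window_um[2]))
    print(x$anova[[nm]])
    cat(sprintf("Permutation group test: P = %.4g\n", x$permutation[[nm]]$p))
  }
  invisible(x)
}

#' Group mean and SEM profile curves
#'
#' Plots the per-group mean of the per-animal profiles with a mean +/- SEM
#' ribbon for one channel, the standard presentation of
#' epithelium-referenced density profiles.
#'
#' @param x a `muco_pipeline`.
#' @param channel channel name (default: first profiled channel).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.muco_pipeline <- function(x, channel = names(x$by_animal)[1], ...) {
  agg <- x$by_animal[[channel]]
  centers <- sort(unique((agg$bin_lo_um + agg$bin_hi_um) / 2))
  groups <- sort(unique(agg$group))
  stats_by <- lapply(groups, function(g) {
    sub <- agg[agg$group == g, ]
    m <- tapply(sub$mean, sub$bin_lo_um, mean)
    s <- tapply(sub$mean, sub$bin_lo_um,
                function(v) stats::sd(v) / sqrt(length(v)))
    list(mean = m, sem = s)
  })
  ylim <- range(unlist(lapply(stats_by, function(s)
    c(s$mean - s$sem, s$mean + s$sem))), na.rm = TRUE)
  cols <- c("#1b6ca8", "#c0392b", "#27ae60", "#8e44ad")
  graphics::plot(NULL, xlim = range(centers), ylim = ylim,
                 xlab = "distance from epithelium (um)",
                 ylab = "normalized density", main = channel, ...)
  for (k in seq_along(groups)) {
    s <- stats_by[[k]]
    graphics::polygon(c(centers, rev(centers)),
                      c(s$mean - s$sem, rev(s$mean + s$sem)),
                      col = grDevices::adjustcolor(cols[k], 0.25),
                      border = NA)
    graphics::lines(centers, s$mean, col = cols[k], lwd = 2)
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   lwd = 2, bty = "n")
  invisible(x)
}
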