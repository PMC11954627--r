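#' Describe one synthetic channel
#'
#' A channel model pairs a channel name with an intensity-versus-distance
#' function and an amplitude.  `diffuse` channels (e.g. MUC2 mucus
#' immunofluorescence) render `amplitude * intensity_fn(d)` directly as
#' expected pixel intensity.  `punctate` channels (e.g. FISH-labelled
#' bacteria) interpret `amplitude * intensity_fn(d)` as a spatial Poisson
#' point-process rate in puncta per square micrometer and render each
#' punctum as a Gaussian blob.
#'
#' @param name channel label (e.g. `"MUC2"`, `"EUB338"`).
#' @param kind `"diffuse"` or `"punctate"`.
#' @param intensity_fn an [intensity_fn] object.
#' @param amplitude non-negative scalar: peak expected intensity (diffuse)
#'   or rate multiplier in puncta/um^2 (punctate).
#' @param puncta_intensity peak rendered intensity of one punctum
#'   (punctate only).
#' @param puncta_sigma Gaussian blob radius of one punctum, micrometers
#'   (punctate only).
#' @return an object of class `channel_model`.
#' @export
channel_model <- function(name, kind = c("diffuse", "punctate"),
                          intensity_fn, amplitude = 1,
                          puncta_intensity = 180, puncta_sigma = 0.4) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop_field("channel name", "must be a non-empty string")
  }
  if (!inherits(intensity_fn, "intensity_fn")) {
    stop_field(paste0("channel '", name, "' intensity_fn"),
               "must be built with an intensity_* constructor")
  }
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop_field(paste0("channel '", name, "' amplitude"),
               "must be non-negative")
  }
  if (puncta_sigma <= 0) {
    stop_field(paste0("channel '", name, "' puncta_sigma"),
               "must be positive")
  }
  structure(list(name = name, kind = kind, intensity_fn = intensity_fn,
                 amplitude = amplitude, puncta_intensity = puncta_intensity,
                 puncta_sigma = puncta_sigma),
            class = "channel_model")
}

#' Configure a synthetic intestinal-section scene
#'
#' Assembles every parameter of the synthetic confocal scene generator: a
#' tissue band of dense DAPI-stained nuclei bounded by a sinusoidal
#' lumen-facing epithelial boundary, one or more signal channels whose
#' expected intensity is a function of distance from that boundary,
#' broadband autofluorescent debris objects in the lumen, a spatially
#' correlated luminal background texture, and mixed Poisson-Gaussian
#' detection noise.
#'
#' @param image_shape integer `(rows, cols)` in pixels.
#' @param pixel_size micrometers per pixel, > 0.
#' @param boundary list: `baseline_um` (depth of the boundary baseline below
#'   the image top; default 60% of the image height), `amplitude_um` and
#'   `period_um` of the sinusoidal boundary, `phase` (radians).  Tissue lies
#'   below the curve, lumen above.
#' @param nuclei list: `density` (nuclei per square micrometer of tissue),
#'   `radius_um` (length-2 range), `intensity` (length-2 range),
#'   `tissue_intensity` (diffuse cytoplasmic DAPI level in tissue).
#' @param channels list of [channel_model()] objects (DAPI is always added).
#' @param debris list: `count`, `radius_um` (length-2 range), `intensity`
#'   (mean broadband level, rendered in every channel including DAPI).
#' @param background list: `sd` (amplitude of the zero-mean correlated
#'   luminal autofluorescence texture added to diffuse channels), `corr_um`
#'   (its correlation length), `offset` (constant luminal DC level).  The
#'   texture emulates unstructured luminal content that does not scale with
#'   the biological signal.
#' @param noise list: `gaussian_sd` (read noise), `poisson_scale` (photons
#'   per intensity unit; 0 disables shot noise).
#' @param animal_cv lognormal coefficient of variation of per-animal channel
#'   amplitudes in [make_group_experiment()].
#' @param center_jitter_um per-animal jitter (SD, micrometers) of Gaussian
#'   intensity-profile centers in [make_group_experiment()].
#' @param seed integer seed making the scene fully reproducible.
#' @return validated object of class `scene_config`.
#' @seealso [generate_scene()], [make_group_experiment()],
#'   [ileum_scene_config()]
#' @export
scene_config <- function(image_shape = c(512L, 512L),
                         pixel_size = 0.5,
                         boundary = list(),
                         nuclei = list(),
                         channels = list(),
                         debris = list(),
                         background = list(),
                         noise = list(),
                         animal_cv = 0.15,
                         center_jitter_um = 0.75,
                         seed = 1L) {
  height_um <- image_shape[1] * pixel_size
  boundary <- utils::modifyList(
    list(baseline_um = 0.6 * height_um, amplitude_um = 12,
         period_um = 170, phase = 0), boundary)
  nuclei <- utils::modifyList(
    list(density = 0.12, radius_um = c(1.5, 3), intensity = c(120, 220),
         tissue_intensity = 60), nuclei)
  debris <- utils::modifyList(
    list(count = 4L, radius_um = c(1.5, 3.5), intensity = 160), debris)
  background <- utils::modifyList(
    list(sd = 24, corr_um = 0.25, offset = 50), background)
  noise <- utils::modifyList(
    list(gaussian_sd = 4, poisson_scale = 0.8), noise)

  cfg <- structure(list(image_shape = as.integer(image_shape),
                        pixel_size = pixel_size, boundary = boundary,
                        nuclei = nuclei, channels = channels,
                        debris = debris, background = background,
                        noise = noise, animal_cv = animal_cv,
                        center_jitter_um = center_jitter_um,
                        seed = as.integer(seed)),
                   class = "scene_config")
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  sh <- cfg$image_shape
  if (length(sh) != 2 || any(!is.finite(sh)) || any(sh < 16)) {
    stop_field("image_shape", "must be two integers >= 16")
  }
  if (!is.numeric(cfg$pixel_size) || cfg$pixel_size <= 0) {
    stop_field("pixel_size", "must be > 0")
  }
  b <- cfg$boundary
  height_um <- sh[1] * cfg$pixel_size
  if (b$amplitude_um < 0 || b$period_um <= 0) {
    stop_field("boundary", "needs amplitude_um >= 0 and period_um > 0")
  }
  if (b$amplitude_um >= min(b$baseline_um, height_um - b$baseline_um)) {
    stop_field("boundary.amplitude_um",
               "must be smaller than the distance from the baseline to the nearest image edge")
  }
  if (any(cfg$nuclei$radius_um <= 0) || cfg$nuclei$density < 0) {
    stop_field("nuclei", "needs positive radii and non-negative density")
  }
  if (cfg$debris$count < 0 || any(cfg$debris$radius_um <= 0)) {
    stop_field("debris", "needs count >= 0 and positive radii")
  }
  if (cfg$background$sd < 0 || cfg$background$corr_um <= 0) {
    stop_field("background", "needs sd >= 0 and corr_um > 0")
  }
  if (cfg$noise$gaussian_sd < 0 || cfg$noise$poisson_scale < 0) {
    stop_field("noise", "needs non-negative gaussian_sd and poisson_scale")
  }
  for (ch in cfg$channels) {
    if (!inherits(ch, "channel_model")) {
      stop_field("channels", "must be a list of channel_model objects")
    }
    if (ch$name == "DAPI") {
      stop_field("channels", "must not redefine the DAPI channel")
    }
  }
  if (anyDuplicated(vapply(cfg$channels, `[[`, "", "name"))) {
    stop_field("channels", "has duplicated channel names")
  }
  cfg
}

#' Default scene emulating distal-ileum sections
#'
#' The flagship configuration used throughout the package: a MUC2-like
#' diffuse mucus channel whose expected intensity peaks 11 um into the
#' lumen (Gaussian, SD 4 um) and an EUB338-like punctate total-bacteria
#' channel whose density decays with distance from the epithelium, over a
#' sinusoidal epithelial boundary.
#'
#' @param image_shape,pixel_size,seed see [scene_config()].
#' @param mucus_amplitude peak expected mucus intensity above background.
#' @param bacteria_rate bacterial point-process rate multiplier
#'   (puncta/um^2 at the epithelium).
#' @param ... further arguments passed to [scene_config()].
#' @return a `scene_config`.
#' @export
ileum_scene_config <- function(image_shape = c(512L, 512L),
                               pixel_size = 0.5,
                               mucus_amplitude = 4,
                               bacteria_rate = 0.02,
                               seed = 1L, ...) {
  scene_config(
    image_shape = image_shape, pixel_size = pixel_size,
    channels = list(
      channel_model("MUC2", "diffuse", intensity_gaussian(11, 4),
                    amplitude = mucus_amplitude),
      channel_model("EUB338", "punctate", intensity_exponential(15),
                    amplitude = bacteria_rate)
    ),
    seed = seed, ...)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %dx%d px @ %.3g um/px, seed %d\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size, x$seed))
  cat(sprintf("  boundary: baseline %.4g um, amplitude %.4g um, period %.4g um\n",
              x$boundary$baseline_um, x$boundary$amplitude_um,
              x$boundary$period_um))
  for (ch in x$channels) {
    cat(sprintf("  channel %s (%s), amplitude %.4g, fn %s\n", ch$name,
                ch$kind, ch$amplitude, attr(ch$intensity_fn, "spec")$form))
  }
  cat(sprintf("  debris: %d objects; noise: gaussian sd %.3g, poisson scale %.3g\n",
              x$debris$count, x$noise$gaussian_sd, x$noise$poisson_scale))
  invisible(x)
}

#' Read or write a scene configuration as YAML
#'
#' Intensity functions are serialized by constructor name and parameters so
#' that a round trip rebuilds an identical generator.
#'
#' @param cfg a `scene_config`.
#' @param path file path.
#' @return `read_scene_config()` returns a `scene_config`;
#'   `write_scene_config()` returns `path` invisibly.
#' @export
write_scene_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scene_config"))
  lst <- unclass(cfg)
  lst$channels <- lapply(cfg$channels, function(ch) {
    list(name = ch$name, kind = ch$kind,
         intensity = attr(ch$intensity_fn, "spec"),
         amplitude = ch$amplitude,
         puncta_intensity = ch$puncta_intensity,
         puncta_sigma = ch$puncta_sigma)
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  lst <- yaml::read_yaml(path)
  channels <- lapply(lst$channels, function(ch) {
    channel_model(ch$name, ch$kind, intensity_from_spec(ch$intensity),
                  ch$amplitude, ch$puncta_intensity, ch$puncta_sigma)
  })
  scene_config(image_shape = unlist(lst$image_shape),
               pixel_size = lst$pixel_size,
               boundary = lst$boundary, nuclei = lapply(lst$nuclei, unlist),
               channels = channels, debris = lapply(lst$debris, unlist),
               background = lst$background, noise = lst$noise,
               animal_cv = lst$animal_cv,
               center_jitter_um = lst$center_jitter_um, seed = lst$seed)
}
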