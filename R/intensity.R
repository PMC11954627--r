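#' Intensity-versus-distance model functions
#'
#' Constructors for the unit-amplitude intensity (or point-process rate)
#' profiles used by [channel_model()].  Each returns an object of class
#' `intensity_fn`: a function of signed distance `d` from the epithelial
#' boundary in micrometers (positive into the lumen) that evaluates to a
#' non-negative value, equal to 0 for `d < 0` (no signal inside tissue).
#' The functional forms mirror the spatial patterns seen in
#' epithelium-referenced profiling of gut sections: a mucus layer peaking a
#' few micrometers into the lumen, bacterial taxa enriched or depleted near
#' the epithelium, and taxa whose relative density crosses over at a
#' characteristic distance.
#'
#' @param center,sd Gaussian peak location and width, micrometers.
#' @param value constant level.
#' @param range half-open interval `[lo, hi)` of distances (micrometers) on
#'   which a constant profile is non-zero.
#' @param scale exponential decay length, micrometers.
#' @param cross crossover distance, micrometers.
#' @param low,high levels below and above the crossover.
#' @param softness logistic transition width at the crossover, micrometers.
#' @return a function of class `intensity_fn` with attributes `spec`
#'   (name + parameters, used for serialization) and `peak` (the distance
#'   at which the function is maximal).
#' @examples
#' f <- intensity_gaussian(center = 11, sd = 4)
#' f(11)   # 1, the unit-amplitude peak
#' f(-5)   # 0, no signal inside tissue
#' @name intensity_fn
NULL

new_intensity_fn <- function(fn, spec, peak) {
  structure(function(d) {
    v <- fn(d)
    v[d < 0] <- 0
    pmax(v, 0)
  }, class = "intensity_fn", spec = spec, peak = peak)
}

#' @rdname intensity_fn
#' @export
intensity_gaussian <- function(center = 11, sd = 4) {
  stopifnot(sd > 0, center >= 0)
  new_intensity_fn(function(d) exp(-(d - center)^2 / (2 * sd^2)),
                   spec = list(form = "gaussian", center = center, sd = sd),
                   peak = center)
}

#' @rdname intensity_fn
#' @export
intensity_constant <- function(value = 1, range = c(0, Inf)) {
  stopifnot(value >= 0, length(range) == 2, range[2] > range[1])
  new_intensity_fn(function(d) value * (d >= range[1] & d < range[2]),
                   spec = list(form = "constant", value = value,
                               range = range),
                   peak = max(range[1], 0))
}

#' @rdname intensity_fn
#' @export
intensity_exponential <- function(scale = 15) {
  stopifnot(scale > 0)
  new_intensity_fn(function(d) exp(-d / scale),
                   spec = list(form = "exponential", scale = scale),
                   peak = 0)
}

#' @rdname intensity_fn
#' @export
intensity_crossover <- function(cross = 10, low = 0.2, high = 1,
                                softness = 1) {
  stopifnot(cross > 0, low >= 0, high >= 0, softness > 0)
  new_intensity_fn(
    function(d) low + (high - low) / (1 + exp(-(d - cross) / softness)),
    spec = list(form = "crossover", cross = cross, low = low, high = high,
                softness = softness),
    peak = if (high >= low) cross + 6 * softness else 0
  )
}

# Rebuild an intensity_fn from its serialized spec (YAML round trip).
intensity_from_spec <- function(spec) {
  switch(spec$form,
    gaussian = intensity_gaussian(spec$center, spec$sd),
    constant = intensity_constant(spec$value, unlist(spec$range)),
    exponential = intensity_exponential(spec$scale),
    crossover = intensity_crossover(spec$cross, spec$low, spec$high,
                                    spec$softness),
    stop_field("intensity_fn", sprintf("has unknown form '%s'", spec$form))
  )
}

#' @export
print.intensity_fn <- function(x, ...) {
  sp <- attr(x, "spec")
  pars <- sp[names(sp) != "form"]
  cat(sprintf("<intensity_fn: %s(%s)>\n", sp$form,
              paste(names(pars), vapply(pars, function(p)
                paste(signif(unlist(p), 4), collapse = ","), ""),
                sep = "=", collapse = ", ")))
  invisible(x)
}
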