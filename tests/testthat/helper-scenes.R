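# Shared fixture builders: everything is generated in code at test time.

# A noise-free, background-free, debris-free scene configuration.
quiet_scene_cfg <- function(image_shape = c(128, 128), pixel_size = 0.5,
                            channels = list(), seed = 1L, ...) {
  scene_config(image_shape = image_shape, pixel_size = pixel_size,
               channels = channels,
               debris = list(count = 0),
               background = list(sd = 0, offset = 0),
               noise = list(gaussian_sd = 0, poisson_scale = 0),
               animal_cv = 0, center_jitter_um = 0,
               seed = seed, ...)
}

# Exhaustive signed distance oracle: min over boundary pixels, O(npix * nb).
bf_distance_field <- function(coords, tissue_mask, pixel_size) {
  nr <- nrow(tissue_mask); nc <- ncol(tissue_mask)
  out <- matrix(0, nr, nc)
  on_b <- matrix(FALSE, nr, nc)
  on_b[coords] <- TRUE
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- sqrt(min((r - coords[, 1])^2 + (c - coords[, 2])^2)) * pixel_size
    s <- if (on_b[r, c]) 0 else if (tissue_mask[r, c]) -1 else 1
    out[r, c] <- if (s == 0) 0 else s * d
  }
  out
}

# Exhaustive per-pixel group-by binning oracle.
bf_bin_means <- function(channel, d, bin_width, lo, hi, exclude = NULL) {
  keep <- d >= lo & d < hi
  if (!is.null(exclude)) keep <- keep & !exclude
  idx <- floor((d[keep] - lo) / bin_width) + 1
  nb <- round((hi - lo) / bin_width)
  means <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    sel <- idx == k
    if (any(sel)) means[k] <- mean(channel[keep][sel])
  }
  means
}

# Random tissue mask + boundary for oracle tests: tissue below a random
# monotone-ish ragged curve.
random_boundary_scene <- function(n = 32, seed = 1) {
  set.seed(seed)
  base <- sample(8:(n - 8), 1)
  rows <- pmin(pmax(base + cumsum(sample(-1:1, n, TRUE)), 3), n - 2)
  tissue <- outer(seq_len(n), rows, `>=`)
  edge <- mucoprofiler:::edge_of_mask(tissue) & tissue
  # keep only the lumen-facing edge (tissue also touches the frame bottom)
  coords <- which(edge, arr.ind = TRUE)
  colnames(coords) <- c("row", "col")
  mucoprofiler:::new_epithelial_boundary(tissue, coords, pixel_size = 0.5)
}

# Half-plane DAPI image: bright tissue rows, dark lumen.
half_plane_dapi <- function(n = 64, split = 32, bright_top = FALSE,
                            level = 120) {
  m <- matrix(0, n, n)
  if (bright_top) m[seq_len(split - 1), ] <- level
  else m[split:n, ] <- level
  m
}
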