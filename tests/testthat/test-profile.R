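test_that("distance field matches the axis-aligned closed form", {
  tm <- matrix(FALSE, 16, 16)
  tm[, 1] <- TRUE
  b <- mucoprofiler:::new_epithelial_boundary(
    tm, cbind(row = 1:16, col = rep(1L, 16)), pixel_size = 1)
  f <- compute_distance_field(b, c(16, 16), 1)
  for (cc in 1:16) expect_equal(unclass(f)[, cc], rep(cc - 1, 16))
})

test_that("distance field equals the brute-force oracle exactly", {
  for (seed in 1:6) {
    b <- random_boundary_scene(24, seed = seed)
    f <- compute_distance_field(b, c(24, 24), 0.5)
    expect_equal(unclass(f),
                 bf_distance_field(b$coords, b$tissue_mask, 0.5),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("distance sign convention: tissue negative, boundary zero", {
  b <- random_boundary_scene(24, seed = 9)
  f <- unclass(compute_distance_field(b, c(24, 24), 0.5))
  on_b <- matrix(FALSE, 24, 24); on_b[b$coords] <- TRUE
  expect_true(all(f[on_b] == 0))
  expect_true(all(f[b$tissue_mask & !on_b] < 0))
  expect_true(all(f[!b$tissue_mask] > 0))
  # a tissue pixel directly below a boundary pixel sits at -pixel_size
  # (pick one whose below-neighbor is not itself on the boundary)
  i <- which(!(paste(b$coords[, 1] + 1, b$coords[, 2]) %in%
                 paste(b$coords[, 1], b$coords[, 2])))[1]
  co <- b$coords[i, ]
  expect_equal(f[co[1] + 1, co[2]], -0.5)
  expect_error(compute_distance_field(
    mucoprofiler:::new_epithelial_boundary(b$tissue_mask,
                                           b$coords[0, , drop = FALSE],
                                           pixel_size = 1)),
    "empty boundary")
})

test_that("binning matches the exhaustive group-by oracle exactly", {
  for (seed in 1:6) {
    b <- random_boundary_scene(24, seed = 20 + seed)
    f <- compute_distance_field(b, c(24, 24), 0.5)
    set.seed(seed)
    ch <- matrix(rnorm(24 * 24), 24, 24)
    p <- bin_profile(ch, f, 1, c(0, 8))
    expect_equal(p$mean, bf_bin_means(ch, unclass(f), 1, 0, 8),
                 tolerance = 1e-12)
    # the channel equal to its own distance reproduces per-bin mean distance
    p2 <- bin_profile(unclass(f), f, 1, c(0, 8))
    expect_equal(p2$mean,
                 bf_bin_means(unclass(f), unclass(f), 1, 0, 8),
                 tolerance = 1e-12)
  }
})

test_that("a uniform channel yields constant bin means and counted pixels", {
  b <- random_boundary_scene(24, seed = 31)
  f <- compute_distance_field(b, c(24, 24), 0.5)
  p <- bin_profile(matrix(7, 24, 24), f, 1, c(0, 6))
  expect_true(all(p$mean[p$n_pixels > 0] == 7))
  expect_equal(sum(p$n_pixels),
               sum(unclass(f) >= 0 & unclass(f) < 6))
})

test_that("exclude masks change bin means exactly as the oracle predicts", {
  b <- random_boundary_scene(24, seed = 32)
  f <- compute_distance_field(b, c(24, 24), 0.5)
  set.seed(2)
  ch <- matrix(runif(24 * 24, 0, 10), 24, 24)
  excl <- matrix(runif(24 * 24) < 0.3, 24, 24)
  p <- bin_profile(ch, f, 1, c(0, 8), exclude_mask = excl)
  expect_equal(p$mean, bf_bin_means(ch, unclass(f), 1, 0, 8, excl),
               tolerance = 1e-12)
})

test_that("binning rejects degenerate ranges", {
  b <- random_boundary_scene(24, seed = 33)
  f <- compute_distance_field(b, c(24, 24), 0.5)
  ch <- matrix(1, 24, 24)
  expect_error(bin_profile(ch, f, 1, c(-10, -2)), "inside tissue")
  expect_error(bin_profile(ch, f, 0, c(0, 8)), "bin_width")
  expect_error(bin_profile(ch, f, 1, c(0, 8.5)), "integer number")
  expect_error(bin_profile(ch, f, 1, c(8, 2)), "hi > lo")
  expect_error(bin_profile(matrix(1, 3, 3), f, 1, c(0, 8)), "shape")
})

test_that("z-normalization gives mean 0, sample SD 1, and is idempotent", {
  p <- mucoprofiler:::new_density_profile(0:3, c(1, 2, 3), c(5, 5, 5),
                                          "toy")
  n1 <- normalize_profile(p)
  expect_equal(n1$mean, c(-1, 0, 1))
  expect_true(n1$normalized)
  expect_identical(n1$n_pixels, p$n_pixels)
  n2 <- normalize_profile(n1)
  expect_equal(n2$mean, n1$mean, tolerance = 1e-12)
  expect_error(normalize_profile(
    mucoprofiler:::new_density_profile(0:3, c(5, 5, 5), c(1, 1, 1), "x")),
    "constant")
  expect_error(normalize_profile(
    mucoprofiler:::new_density_profile(0:1, 5, 1, "x")), "2 non-missing")
})

test_that("normalization invariant holds for randomly generated profiles", {
  set.seed(77)
  for (i in 1:20) {
    nb <- sample(5:40, 1)
    means <- rnorm(nb, sd = runif(1, 0.5, 20))
    means[sample(nb, sample(0:2, 1))] <- NA
    p <- mucoprofiler:::new_density_profile(0:nb, means,
                                            rep(10L, nb), "rand")
    n <- normalize_profile(p)
    ok <- !is.na(n$mean)
    expect_lt(abs(mean(n$mean[ok])), 1e-9)
    expect_lt(abs(stats::sd(n$mean[ok]) - 1), 1e-9)
  }
})

test_that("window extraction counts bins and enforces alignment", {
  p <- mucoprofiler:::new_density_profile(0:100, rnorm(100),
                                          rep(1L, 100), "toy")
  w <- extract_window(p, 0, 20)
  expect_length(w$mean, 20)
  expect_equal(w$bin_edges, 0:20)
  expect_identical(extract_window(p, 0, 100)$mean, p$mean)
  expect_error(extract_window(p, 7.5, 20), "aligned")
  expect_error(extract_window(p, 20, 20), "aligned|empty")
})

test_that("peak finding is argmax with ties toward the epithelium", {
  mk <- function(means) mucoprofiler:::new_density_profile(
    seq(0, length(means)), means, rep(1L, length(means)), "toy")
  expect_equal(find_peak(mk(c(9, 7, 5, 3)))$peak_distance, 0.5)
  two <- rep(0, 12); two[c(6, 10)] <- 4   # equal maxima at 5.5 and 9.5 um
  expect_equal(find_peak(mk(two))$peak_distance, 5.5)
  expect_error(find_peak(mk(c(NA, NA))), "missing")
})

test_that("zero-noise Gaussian mucus profiles match the analytic curve", {
  fn <- intensity_gaussian(11, 4)
  cfg <- quiet_scene_cfg(c(512, 512), pixel_size = 0.125,
                         boundary = list(amplitude_um = 12, period_um = 85),
                         channels = list(channel_model("MUC2", "diffuse",
                                                       fn, amplitude = 10)),
                         seed = 11)
  sc <- generate_scene(cfg)
  p <- bin_profile(sc$image$channels$MUC2, sc$truth$distance_um, 1,
                   c(0, 30), channel_name = "MUC2")
  ctr <- bin_centers(p)
  expected <- 10 * fn(ctr)
  # skip the bin straddling the rasterized boundary (center 0.5 um), where
  # pixel-center quantization dominates; compare where the curve is
  # appreciably non-zero
  sel <- ctr > 1 & ctr <= 22
  expect_lt(max(abs(p$mean[sel] - expected[sel]) / expected[sel]), 0.02)
  expect_equal(find_peak(p)$peak_distance, 11.5, tolerance = 1)
  # resolution stability: halving the bin width moves the peak <= 1 bin
  p_half <- bin_profile(sc$image$channels$MUC2, sc$truth$distance_um, 0.5,
                        c(0, 30))
  expect_lt(abs(find_peak(p_half)$peak_distance -
                  find_peak(p)$peak_distance), 1 + 1e-9)
})

test_that("per-animal aggregation is the bin-wise mean over images", {
  grid <- data.frame(bin_lo_um = c(0, 1), bin_hi_um = c(1, 2))
  row <- function(img, animal, grp, m) {
    data.frame(image = img, animal = animal, group = grp,
               channel = "MUC2", bin_lo_um = grid$bin_lo_um,
               bin_hi_um = grid$bin_hi_um, mean = m, n_pixels = 10L,
               normalized = TRUE)
  }
  df <- rbind(row("i1", "a1", "A", c(1, 3)), row("i2", "a1", "A", c(3, 5)),
              row("i3", "b1", "B", c(2, NA)))
  agg <- aggregate_by_animal(df)
  a1 <- agg[agg$animal == "a1", ]
  expect_equal(a1$mean[order(a1$bin_lo_um)], c(2, 4))
  expect_true(is.na(agg$mean[agg$animal == "b1" & agg$bin_lo_um == 1]))
  expect_equal(unique(agg$n_images[agg$animal == "a1"]), 2)
  # single image per animal: aggregation is the identity
  one <- aggregate_by_animal(row("i9", "c1", "A", c(4, 6)))
  expect_equal(one$mean[order(one$bin_lo_um)], c(4, 6))
  # mixed bin grids are rejected
  bad <- rbind(row("i1", "a1", "A", c(1, 3)),
               transform(row("i2", "a2", "B", c(1, 3)),
                         bin_lo_um = bin_lo_um + 0.5,
                         bin_hi_um = bin_hi_um + 0.5))
  expect_error(aggregate_by_animal(bad), "mixed bin grids")
})
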