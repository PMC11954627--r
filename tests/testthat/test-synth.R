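test_that("identical config and seed give bit-identical scenes", {
  cfg <- ileum_scene_config(c(96, 96), seed = 17)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$boundary_coords, b$truth$boundary_coords)
  expect_identical(a$truth$debris_mask, b$truth$debris_mask)
  expect_identical(a$truth$centroids, b$truth$centroids)
  c2 <- generate_scene(ileum_scene_config(c(96, 96), seed = 18))
  expect_false(identical(a$image$channels, c2$image$channels))
})

test_that("a constant diffuse channel renders as an exact flat field", {
  fn <- intensity_constant(5, c(0, 50))
  cfg <- quiet_scene_cfg(c(128, 128), channels = list(
    channel_model("flat", "diffuse", fn, amplitude = 1)), seed = 2)
  sc <- generate_scene(cfg)
  d <- unclass(sc$truth$distance_um)
  luminal <- d > 0 & d < 50
  expect_true(all(sc$image$channels$flat[luminal] == 5))
  expect_true(all(sc$image$channels$flat[d < 0] == 0))
})

test_that("noise-free diffuse rendering equals intensity_fn of the distance", {
  fn <- intensity_gaussian(11, 4)
  cfg <- quiet_scene_cfg(c(128, 128), channels = list(
    channel_model("MUC2", "diffuse", fn, amplitude = 7)), seed = 3)
  sc <- generate_scene(cfg)
  d <- unclass(sc$truth$distance_um)
  expect_equal(sc$image$channels$MUC2, 7 * matrix(fn(as.vector(d)),
                                                  nrow(d), ncol(d)))
})

test_that("boundary coords lie on the tissue-mask edge and form a chain", {
  sc <- generate_scene(ileum_scene_config(c(128, 128), seed = 5))
  co <- sc$truth$boundary_coords
  expect_true(all(sc$truth$tissue_mask[co]))
  edge <- mucoprofiler:::edge_of_mask(sc$truth$tissue_mask)
  expect_true(all(edge[co]))
  steps <- pmax(abs(diff(co[, 1])), abs(diff(co[, 2])))
  expect_true(all(steps == 1))  # ordered 8-connected chain
})

test_that("punctate rendering follows the configured point-process rate", {
  rate <- 1
  cfg <- quiet_scene_cfg(c(512, 512), channels = list(
    channel_model("EUB338", "punctate", intensity_constant(1, c(0, 40)),
                  amplitude = rate)), seed = 8)
  sc <- generate_scene(cfg)
  d <- unclass(sc$truth$distance_um)
  ctr <- sc$truth$centroids$EUB338
  expect_gt(nrow(ctr), 9000)
  d_pt <- d[cbind(ctr$row, ctr$col)]
  edges <- seq(0, 40, by = 5)
  obs <- as.vector(table(cut(d_pt, edges, right = FALSE)))
  area <- vapply(seq_len(length(edges) - 1), function(k) {
    sum(d >= edges[k] & d < edges[k + 1]) * 0.5^2
  }, 0)
  expected <- rate * area
  chi2 <- sum((obs - expected)^2 / expected)
  p <- stats::pchisq(chi2, df = length(obs), lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("debris ground truth is luminal and disjoint from puncta", {
  cfg <- ileum_scene_config(c(192, 192), seed = 21)
  cfg$debris$count <- 12
  sc <- generate_scene(cfg)
  expect_false(any(sc$truth$debris_mask & sc$truth$tissue_mask))
  ctr <- sc$truth$centroids$EUB338
  expect_false(any(sc$truth$debris_mask[cbind(ctr$row, ctr$col)]))
  expect_equal(nrow(sc$truth$debris_table), 12)
})

test_that("group experiments scale amplitudes by the effect ratio", {
  cfg <- quiet_scene_cfg(c(128, 128), channels = list(
    channel_model("MUC2", "diffuse", intensity_gaussian(11, 4),
                  amplitude = 6)), seed = 1)
  ex <- make_group_experiment(cfg, n_per_group = 5, effect = 3, seed = 101)
  expect_length(ex$scenes, 10)
  expect_equal(as.vector(table(ex$meta$group)), c(5, 5))
  # group-mean peak ratio: analytic oracle is the amplitude ratio, since
  # the noise-free rendered peak equals the per-animal amplitude
  peak_of <- function(sc) {
    p <- bin_profile(sc$image$channels$MUC2, sc$truth$distance_um, 1,
                     c(0, 30))
    find_peak(p)$peak_value
  }
  peaks <- vapply(ex$scenes, peak_of, 0)
  ratio <- mean(peaks[ex$meta$group == "B"]) / mean(peaks[ex$meta$group == "A"])
  expect_equal(ratio, 3, tolerance = 0.02)
})

test_that("experiments are reproducible from the master seed and reject bad n", {
  cfg <- ileum_scene_config(c(96, 96), seed = 1)
  e1 <- make_group_experiment(cfg, 2, effect = 2, seed = 55)
  e2 <- make_group_experiment(cfg, 2, effect = 2, seed = 55)
  expect_identical(lapply(e1$scenes, function(s) s$image$channels),
                   lapply(e2$scenes, function(s) s$image$channels))
  expect_identical(e1$meta, e2$meta)
  expect_error(make_group_experiment(cfg, 0, effect = 2), "n_per_group")
  expect_error(make_group_experiment(cfg, 2, effect = -1), "effect")
})

test_that("invalid configurations name the offending field", {
  expect_error(scene_config(pixel_size = 0), "pixel_size")
  expect_error(scene_config(boundary = list(amplitude_um = 200)),
               "amplitude_um")
  expect_error(scene_config(debris = list(count = -1)), "debris")
  expect_error(scene_config(nuclei = list(radius_um = c(0, 2))), "nuclei")
})

test_that("scene configurations round-trip through YAML", {
  cfg <- ileum_scene_config(c(96, 96), seed = 33)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_config(cfg, path)
  cfg2 <- read_scene_config(path)
  expect_identical(generate_scene(cfg)$image$channels,
                   generate_scene(cfg2)$image$channels)
})
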