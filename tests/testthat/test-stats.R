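make_pm <- function(n = 5, b = 10, shift = 0, seed = 1) {
  set.seed(seed)
  animals <- paste0("a", seq_len(2 * n))
  agg <- expand.grid(animal = animals, bin_lo_um = 0:(b - 1),
                     stringsAsFactors = FALSE)
  agg$bin_hi_um <- agg$bin_lo_um + 1
  agg$group <- ifelse(match(agg$animal, animals) <= n, "A", "B")
  agg$mean <- rnorm(nrow(agg)) + shift * (agg$group == "B")
  profile_matrix(agg)
}

test_that("the 2x2x2 toy design matches the pencil-and-paper decomposition", {
  # 2 groups x 2 bins x 2 animals, values 1..8 assigned in reading order:
  # A1=(1,2) A2=(3,4) B1=(5,6) B2=(7,8)  (animal = row, bin = column)
  agg <- data.frame(
    animal = rep(c("A1", "A2", "B1", "B2"), each = 2),
    group = rep(c("A", "B"), each = 4),
    bin_lo_um = rep(c(0, 1), 4), bin_hi_um = rep(c(1, 2), 4),
    mean = 1:8)
  y <- matrix(1:8, ncol = 2, byrow = TRUE)     # rows = animals
  grand <- mean(y)
  ss_group <- 4 * ((mean(y[1:2, ]) - grand)^2 + (mean(y[3:4, ]) - grand)^2)
  ss_bin <- 4 * ((mean(y[, 1]) - grand)^2 + (mean(y[, 2]) - grand)^2)
  cell_means <- rbind(colMeans(y[1:2, ]), colMeans(y[3:4, ]))
  ss_cells <- 2 * sum((cell_means - grand)^2)
  ss_int <- ss_cells - ss_group - ss_bin
  ss_res <- sum((y - cell_means[rep(1:2, each = 2), ])^2)
  fit <- two_way_anova(profile_matrix(agg))
  tab <- fit$table
  expect_equal(tab["group", "Sum Sq"], ss_group, tolerance = 1e-12)
  expect_equal(tab["distance", "Sum Sq"], ss_bin, tolerance = 1e-12)
  expect_equal(tab["group:distance", "Sum Sq"], ss_int, tolerance = 1e-12)
  expect_equal(tab["Residuals", "Sum Sq"], ss_res, tolerance = 1e-12)
  expect_equal(sum(tab[, "Df"]), 8 - 1)
  expect_equal(sum(tab[, "Sum Sq"]), sum((y - grand)^2), tolerance = 1e-9)
  f_group <- (ss_group / 1) / (ss_res / 4)
  expect_equal(tab["group", "F value"], f_group, tolerance = 1e-12)
  expect_equal(tab["group", "Pr(>F)"],
               stats::pf(f_group, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs raise the documented errors", {
  # group B = group A + constant shift, no noise: zero residual SS
  agg <- data.frame(animal = rep(c("A1", "A2", "B1", "B2"), each = 2),
                    group = rep(c("A", "B"), each = 4),
                    bin_lo_um = rep(c(0, 1), 4),
                    bin_hi_um = rep(c(1, 2), 4),
                    mean = c(1, 2, 1, 2, 4, 5, 4, 5))
  expect_error(two_way_anova(profile_matrix(agg)), "residual")
  # one animal per group
  one <- data.frame(animal = rep(c("A1", "B1"), each = 2),
                    group = rep(c("A", "B"), each = 2),
                    bin_lo_um = rep(c(0, 1), 2),
                    bin_hi_um = rep(c(1, 2), 2), mean = c(1, 2, 3, 5))
  expect_error(two_way_anova(profile_matrix(one)), "2 animals")
  # a missing cell names the offending cell
  holes <- make_pm(n = 3, b = 4)
  holes$values[1, 2] <- NA
  expect_error(two_way_anova(holes), "group=A")
})

test_that("closed-form permutation statistic reproduces the aov F", {
  for (seed in 1:4) {
    pm <- make_pm(n = 4, b = 6, shift = 0.3, seed = seed)
    fit <- two_way_anova(pm)
    expect_equal(mucoprofiler:::group_f_stat(pm$values, pm$group),
                 fit$table["group", "F value"], tolerance = 1e-9)
  }
  # unbalanced groups (full bin grids) still agree
  pm <- make_pm(n = 4, b = 6, shift = 0.3, seed = 9)
  pm$values <- pm$values[-1, ]
  pm$group <- factor(pm$group[-1])
  long <- mucoprofiler:::pm_long(pm)
  f_aov <- summary(stats::aov(value ~ group * distance, long))[[1]]
  expect_equal(mucoprofiler:::group_f_stat(pm$values, pm$group),
               f_aov[1, "F value"], tolerance = 1e-9)
})

test_that("permutation p-values are reproducible and sensible", {
  pm <- make_pm(n = 5, b = 8, shift = 1.2, seed = 3)
  p1 <- permutation_group_test(pm, n_perm = 499, seed = 7)
  p2 <- permutation_group_test(pm, n_perm = 499, seed = 7)
  expect_identical(p1, p2)
  expect_lt(p1$p, 0.05)
  pm0 <- make_pm(n = 5, b = 8, shift = 0, seed = 4)
  expect_gt(permutation_group_test(pm0, n_perm = 499, seed = 7)$p, 0.05)
})

test_that("pointwise comparison matches the closed-form Welch t", {
  agg <- data.frame(animal = paste0("m", 1:6),
                    group = rep(c("WT", "KI"), each = 3),
                    bin_lo_um = 10, bin_hi_um = 11,
                    mean = c(1, 2, 3, 4, 5, 6))
  agg <- rbind(agg, transform(agg, bin_lo_um = 11, bin_hi_um = 12,
                              mean = mean + 0.5))
  pm <- profile_matrix(agg)
  cmp <- compare_at_distance(pm, 10.5)
  x <- c(4, 5, 6); y <- c(1, 2, 3)   # levels sort KI before WT
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_stat <- (mean(y) - mean(x)) / se
  df <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(cmp$statistic, t_stat, tolerance = 1e-12)
  expect_equal(cmp$p, 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(cmp$groups$mean, c(mean(x), mean(y)))
  expect_equal(cmp$groups$sd, c(1, 1))
  expect_error(compare_at_distance(pm, 99), "not on the bin grid")
})

test_that("identical groups give zero difference and zero statistic", {
  agg <- data.frame(animal = paste0("m", 1:6),
                    group = rep(c("A", "B"), each = 3),
                    bin_lo_um = 0, bin_hi_um = 1,
                    mean = rep(c(1, 2, 3), 2))
  agg <- rbind(agg, transform(agg, bin_lo_um = 1, bin_hi_um = 2))
  cmp <- compare_at_distance(profile_matrix(agg), 0.5)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$statistic, 0)
})

test_that("reports are deterministic and rebuildable from saved CSV", {
  pm <- make_pm(n = 4, b = 6, shift = 0.8, seed = 5)
  agg <- data.frame(animal = rep(rownames(pm$values), ncol(pm$values)),
                    group = rep(as.character(pm$group), ncol(pm$values)),
                    bin_lo_um = rep(pm$bin_lo_um, each = nrow(pm$values)),
                    bin_hi_um = rep(pm$bin_hi_um, each = nrow(pm$values)),
                    mean = as.vector(pm$values))
  fit <- two_way_anova(pm)
  perm <- permutation_group_test(pm, 199, seed = 2)
  cmp <- list(compare_at_distance(pm, 0.5))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  profile_report(agg, fit, perm, cmp, config = list(seed = 2),
                 out_dir = d1)
  profile_report(agg, fit, perm, cmp, config = list(seed = 2),
                 out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # regeneration from the saved per-animal CSV, without images
  agg_back <- utils::read.csv(file.path(d1, "profiles_by_animal.csv"))
  fit_back <- two_way_anova(profile_matrix(agg_back))
  expect_equal(fit_back$table, fit$table, tolerance = 1e-12)
  expect_error(profile_report(NULL, fit), "missing upstream")
  expect_error(profile_report(agg, NULL), "ANOVA")
})
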