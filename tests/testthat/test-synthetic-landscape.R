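test_that("climate stack generation is deterministic and respects correlation targets", {
  a <- generate_climate_stack(3, shape = c(60, 60), autocorr_range = 8,
                              cross_corr = 0.5, seed = 11)
  b <- generate_climate_stack(3, shape = c(60, 60), autocorr_range = 8,
                              cross_corr = 0.5, seed = 11)
  expect_identical(a$layers, b$layers)

  # independent layers: empirical correlation near zero on >= 10^4 cells
  z <- generate_climate_stack(2, shape = c(120, 120), autocorr_range = 3,
                              cross_corr = 0, seed = 12)
  r <- cor(as.vector(z$layers[[1]]), as.vector(z$layers[[2]]))
  expect_lt(abs(r), 0.1)

  # strong positive target is reflected empirically
  hi <- generate_climate_stack(2, shape = c(120, 120), autocorr_range = 3,
                               cross_corr = 0.8, seed = 12)
  expect_gt(cor(as.vector(hi$layers[[1]]), as.vector(hi$layers[[2]])), 0.6)

  # block correlation matrix: high within blocks, low between
  bl <- matrix(0, 4, 4); bl[1:2, 1:2] <- 0.9; bl[3:4, 3:4] <- 0.9
  diag(bl) <- 1
  bst <- generate_climate_stack(4, shape = c(120, 120), autocorr_range = 3,
                                cross_corr = bl, seed = 14)
  cm <- cor(vapply(bst$layers, as.vector, numeric(120^2)))
  expect_gt(cm[1, 2], 0.7)
  expect_gt(cm[3, 4], 0.7)
  expect_lt(abs(cm[1, 3]), 0.2)
  expect_error(generate_climate_stack(4, cross_corr = matrix(1, 4, 4)),
               class = "invalid_parameter")
})

test_that("smoothing limit: very large autocorrelation range flattens layers", {
  # the raw smoothed field is near-constant; variance far below white noise
  set.seed(13)
  raw <- disjunctSDM:::gauss_smooth(matrix(rnorm(1600), 40, 40), 400)
  expect_lt(var(as.vector(raw)), 0.05)  # white-noise variance is 1
  expect_error(generate_climate_stack(1, shape = c(40, 40)),
               class = "invalid_parameter")
  expect_error(generate_climate_stack(3, shape = c(40, 40), autocorr_range = -1),
               class = "invalid_parameter")
})

test_that("future stacks are controlled perturbations of the current stack", {
  st <- test_landscape()$stack
  same <- generate_future_stack(st, shift = list(), noise_sd = 0, gcm = "G",
                                rcp = "r")
  expect_equal(same$layers, st$layers)
  expect_identical(same$scenario_id, "G_r")

  up <- generate_future_stack(st, shift = list(env2 = list(offset = 2)),
                              noise_sd = 0)
  expect_equal(mean(up$layers$env2) - mean(st$layers$env2), 2, tolerance = 1e-12)
  expect_equal(up$layers$env1, st$layers$env1)

  expect_error(generate_future_stack(st, shift = list(nope = list(offset = 1))),
               class = "unknown_layer")

  # two seeds differ only in the smooth noise component; short-range noise
  # keeps enough independent patches for the variance arithmetic to hold
  f1 <- generate_future_stack(st, noise_sd = 0.3, seed = 21, autocorr_range = 3)
  f2 <- generate_future_stack(st, noise_sd = 0.3, seed = 22, autocorr_range = 3)
  dif <- as.vector(f1$layers$env1 - f2$layers$env1)
  expect_lt(abs(mean(dif)), 0.05)
  expect_equal(sd(dif), sqrt(2) * 0.3, tolerance = 0.1)
})

test_that("virtual-species sampling follows the truth suitability", {
  fx <- test_landscape()
  occ <- fx$occ
  expect_identical(sort(unique(occ$group)), c("core", "disjunct"))
  expect_equal(sum(occ$group == "core"), 150)

  # every point lies inside its declared region and off nodata
  rc <- point_cells(fx$stack, occ$x, occ$y)
  idx <- cbind(rc$row, rc$col)
  core_i <- occ$group == "core"
  expect_true(all(fx$truth$region_masks$core[idx[core_i, ]]))
  expect_true(all(fx$truth$region_masks$disjunct[idx[!core_i, ]]))
  expect_false(any(fx$stack$nodata[idx]))

  # niche preference: mean suitability at samples exceeds the region mean
  suit_at <- fx$truth$suitability[idx[core_i, ]]
  region_mean <- mean(fx$truth$suitability[fx$truth$region_masks$core],
                      na.rm = TRUE)
  expect_gt(mean(suit_at), region_mean)

  expect_equal(nrow(sample_occurrences(fx$truth, fx$stack, 0, 10, seed = 1)),
               10)
  expect_true(all(sample_occurrences(fx$truth, fx$stack, 0, 10,
                                     seed = 1)$group == "disjunct"))
  expect_error(sample_occurrences(fx$truth, fx$stack, 10^6, 0, seed = 1),
               class = "capacity_error")

  # determinism
  expect_identical(sample_occurrences(fx$truth, fx$stack, 50, 10, seed = 7),
                   sample_occurrences(fx$truth, fx$stack, 50, 10, seed = 7))
})

test_that("uniform truth yields spatially uniform occurrences within a region", {
  st <- generate_climate_stack(2, shape = c(60, 120), autocorr_range = 6,
                               cross_corr = 0, seed = 31)
  flat <- virtual_truth(st, optimum = c(env1 = 0), breadth = c(env1 = Inf),
                        gap_km = 10)
  occ <- sample_occurrences(flat, st, n_core = 2000, n_disjunct = 0, seed = 32)
  # chi-square GOF against uniform across 10 column bands of the core region
  rc <- point_cells(st, occ$x, occ$y)
  core_cols <- which(apply(flat$region_masks$core, 2, any))
  br <- seq(min(core_cols) - 0.5, max(core_cols) + 0.5, length.out = 11)
  band <- table(cut(rc$col, br))
  cells_per_band <- table(cut(core_cols, br))
  p <- suppressWarnings(
    chisq.test(band, p = as.numeric(cells_per_band) /
                 sum(cells_per_band))$p.value)
  expect_gt(p, 0.01)
})

test_that("occurrence layer means converge to the truth-weighted mean", {
  # a large region keeps the without-replacement sampling fraction small, so
  # the weighted-mean identity holds to Monte-Carlo accuracy
  st <- generate_climate_stack(3, shape = c(100, 240), autocorr_range = 8,
                               cross_corr = 0.2, seed = 34)
  tr <- virtual_truth(st, optimum = c(env1 = 0.4, env2 = -0.2),
                      breadth = c(env1 = 0.8, env2 = 0.8), gap_km = 30)
  occ <- sample_occurrences(tr, st, n_core = 600, n_disjunct = 0, seed = 33)
  vals <- extract_values(st, occ$x, occ$y)
  core <- tr$region_masks$core
  w <- tr$suitability[core]
  for (nm in c("env1", "env2")) {
    target <- sum(w * st$layers[[nm]][core]) / sum(w)
    se <- sd(vals[, nm]) / sqrt(nrow(vals))
    expect_lt(abs(mean(vals[, nm]) - target), 3 * se)
  }
})

test_that("area-ratio shift calibration hits its target", {
  fx <- test_landscape()
  off <- shift_for_area_ratio(fx$truth, fx$stack, "env1", target_ratio = 0.5)
  expect_equal(attr(off, "ratio"), 0.5, tolerance = 0.02)
  expect_error(shift_for_area_ratio(fx$truth, fx$stack, "env3"),
               class = "unknown_layer")
})
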