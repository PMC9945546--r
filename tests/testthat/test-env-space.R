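test_that("pooled PCA shares one projection across scenarios", {
  st <- test_landscape()$stack
  # futures identical to current -> identical score grids
  same <- scenario_set(st, list(
    generate_future_stack(st, noise_sd = 0, gcm = "G1", rcp = "r1"),
    generate_future_stack(st, noise_sd = 0, gcm = "G2", rcp = "r1")))
  pr <- pooled_pca(same)
  expect_equal(pr$scores$current, pr$scores$G1_r1)
  expect_equal(pr$scores$current, pr$scores$G2_r1)

  # eigenvalues account for all pooled variance
  expect_equal(sum(pr$explained_var), 1, tolerance = 1e-9)
  expect_true(all(diff(pr$explained_var) <= 1e-12))

  # loadings columns are orthonormal
  g <- crossprod(pr$loadings)
  expect_equal(g, diag(2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("redundant layers concentrate variance on PC1 and degenerate layers are named", {
  base <- matrix(rnorm(900), 30, 30)
  st <- climate_stack(list(a = base, b = base * 2 + 1,  # perfectly correlated
                           c = matrix(rnorm(900), 30, 30),
                           d = matrix(rnorm(900), 30, 30)))
  pr <- pooled_pca(scenario_set(st, list(
    generate_future_stack(st, noise_sd = 0, gcm = "G", rcp = "r"))))
  expect_gt(pr$explained_var[1], 1 / 4)

  flat <- climate_stack(list(a = base, z = matrix(5, 30, 30)))
  err <- tryCatch(pooled_pca(scenario_set(flat, list())),
                  error = function(e) conditionMessage(e))
  expect_match(err, "z")
})

test_that("occurrence density is a normalized, order- and scale-invariant occupancy surface", {
  set.seed(51)
  bg <- cbind(runif(2000, -2, 2), runif(2000, -2, 2))
  occ <- cbind(rnorm(200, 0.5, 0.3), rnorm(200, -0.5, 0.3))
  grid <- env_grid(list(bg), R = 60)
  d1 <- occurrence_density(occ, bg, grid)
  expect_equal(sum(d1$z), 1, tolerance = 1e-9)
  expect_true(all(d1$z >= 0))
  expect_true(all(d1$z[!d1$support] == 0))

  # order invariance
  d2 <- occurrence_density(occ[sample.int(200), ], bg, grid)
  expect_equal(d1$z, d2$z, tolerance = 1e-12)

  # doubling every occurrence leaves the density unchanged
  d3 <- occurrence_density(rbind(occ, occ), bg, grid)
  expect_equal(d1$z, d3$z, tolerance = 1e-12)

  # mode lies within one bandwidth of a tight cluster's centroid
  tight <- cbind(rnorm(50, 1, 0.02), rnorm(50, 1, 0.02))
  dt <- occurrence_density(tight, bg, grid)
  ij <- which(dt$z == max(dt$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(dt$grid$x[ij[1]] - 1), dt$bandwidth[1] + 1e-9)
  expect_lt(abs(dt$grid$y[ij[2]] - 1), dt$bandwidth[2] + 1e-9)

  expect_error(occurrence_density(occ[1:3, ], bg, grid),
               class = "too_few_points")
  expect_error(occurrence_density(occ + 100, bg, grid), class = "off_grid")
})

test_that("grid KDE agrees with the MASS::kde2d oracle", {
  skip_if_not_installed("MASS")
  set.seed(52)
  pts <- cbind(rnorm(300), rnorm(300, 1, 2))
  grid <- structure(list(xlim = c(-4, 4), ylim = c(-6, 8), R = 25,
                         x = seq(-4, 4, length.out = 25),
                         y = seq(-6, 8, length.out = 25)),
                    class = "env_grid")
  bw <- c(0.4, 0.7)
  ours <- disjunctSDM:::kde_on_grid(pts, grid, bw)
  # kde2d's h is the full kernel width, 4x the Gaussian sd it applies
  oracle <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * bw, n = 25,
                        lims = c(grid$xlim, grid$ylim))
  expect_equal(ours, oracle$z, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("occurrences drawn uniformly from the background give a flat occupancy", {
  set.seed(53)
  bg <- cbind(runif(4000, -1, 1), runif(4000, -1, 1))
  occ <- bg[sample.int(4000, 3000, replace = TRUE), ]
  grid <- env_grid(list(bg), R = 40)
  d <- occurrence_density(occ, bg, grid)
  core <- d$z[8:33, 8:33]  # away from the support margin
  expect_lt(max(core) / mean(core), 3)
})

test_that("occupancy centroid recovers a known niche optimum", {
  set.seed(54)
  ns <- niche_sample(1000, opt = c(0.8, -0.5), sdev = c(0.5, 0.5))
  grid <- env_grid(list(ns$background), R = 60)
  d <- occurrence_density(ns$presences, ns$background, grid)
  cx <- sum(outer(d$grid$x, rep(1, 60)) * d$z)
  cy <- sum(outer(rep(1, 60), d$grid$y) * d$z)
  expect_lt(abs(cx - 0.8), 0.25 * 0.5)
  expect_lt(abs(cy + 0.5), 0.25 * 0.5)
})
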