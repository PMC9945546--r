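# Shared fixtures, built in code and memoised per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Small landscape used by most module tests: 80 x 80 km, 4 layers.
test_landscape <- function() memo("landscape", {
  stack <- generate_climate_stack(4, shape = c(80, 80), autocorr_range = 10,
                                  cross_corr = 0.2, seed = 401)
  truth <- virtual_truth(stack, optimum = c(env1 = 0.6, env2 = -0.4),
                         breadth = c(env1 = 0.6, env2 = 0.6), gap_km = 15)
  occ <- sample_occurrences(truth, stack, n_core = 150, n_disjunct = 40,
                            seed = 402)
  list(stack = stack, truth = truth, occ = occ)
})

# Scenario set with two GCMs of one RCP, shifted on env1.
test_scenarios <- function() memo("scenarios", {
  st <- test_landscape()$stack
  futs <- lapply(1:2, function(g)
    generate_future_stack(st, shift = list(env1 = list(offset = 0.6)),
                          noise_sd = 0.05, seed = 410 + g,
                          gcm = paste0("GCM", g), rcp = "rcp85"))
  scenario_set(st, futs)
})

test_projection <- function() memo("projection", pooled_pca(test_scenarios()))

# Niche density object with an arbitrary nonnegative surface, normalized.
fake_density <- function(z, grid = NULL, group = "a") {
  R <- nrow(z)
  if (is.null(grid))
    grid <- structure(list(xlim = c(0, 1), ylim = c(0, 1), R = R,
                           x = seq(0, 1, length.out = R),
                           y = seq(0, 1, length.out = R)),
                      class = "env_grid")
  structure(list(grid = grid, z = z / sum(z), bandwidth = c(0.1, 0.1),
                 group = group, support = z > 0),
            class = "niche_density")
}

random_density <- function(R = 20) {
  z <- matrix(stats::rexp(R * R), R, R)
  fake_density(z)
}

# Presence/background score sets drawn from a log-quadratic (Gaussian) niche
# over a uniform background square; the analytic optimum is `opt`.
niche_sample <- function(n_pres, n_bg = 4000, opt = c(0.8, -0.5),
                         sdev = c(0.5, 0.5), lim = 3) {
  bg <- cbind(stats::runif(n_bg, -lim, lim), stats::runif(n_bg, -lim, lim))
  suit <- exp(-((bg[, 1] - opt[1])^2 / (2 * sdev[1]^2) +
                  (bg[, 2] - opt[2])^2 / (2 * sdev[2]^2)))
  pres <- bg[sample.int(n_bg, n_pres, replace = TRUE, prob = suit), ,
             drop = FALSE]
  list(presences = pres, background = bg)
}

binary_from_matrix <- function(m, scenario_id = "current") {
  structure(list(scenario_id = scenario_id, values = m,
                 threshold_rule = "manual", threshold_value = 0.5),
            class = "binary_map")
}

expect_dsdm_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

# one small end-to-end run shared by the blocks below
pipeline_fixture <- function() memo("pipeline_run", {
  fx <- test_landscape()
  futs <- list(
    generate_future_stack(fx$stack, shift = list(env1 = list(offset = 0.6)),
                          noise_sd = 0.05, seed = 501, gcm = "GCM1",
                          rcp = "rcp26"),
    generate_future_stack(fx$stack, shift = list(env1 = list(offset = 0.6)),
                          noise_sd = 0.05, seed = 502, gcm = "GCM2",
                          rcp = "rcp26"),
    generate_future_stack(fx$stack, shift = list(env1 = list(offset = 1.2)),
                          noise_sd = 0.05, seed = 503, gcm = "GCM1",
                          rcp = "rcp85"))
  ss <- scenario_set(fx$stack, futs)
  cfg <- pipeline_config(seed = 42, buffers_km = 10, env_grid_R = 50,
                         n_background = 1500, n_cv = 4,
                         similarity_reps = 19)
  list(scenarios = ss, config = cfg,
       result = run_species_analysis(ss, fx$occ, cfg))
})

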