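test_that("pseudo-absence sampling is uniform, exhaustive and seeded", {
  st <- test_landscape()$stack
  expect_equal(nrow(sample_pseudoabsences(st, 0, seed = 1)), 0L)
  all_cells <- sample_pseudoabsences(st, sum(!st$nodata), seed = 1)
  expect_equal(nrow(all_cells), sum(!st$nodata))
  expect_false(any(duplicated(all_cells[, c("row", "col")])))
  expect_identical(sample_pseudoabsences(st, 500, seed = 3),
                   sample_pseudoabsences(st, 500, seed = 3))
  expect_error(sample_pseudoabsences(st, sum(!st$nodata) + 1),
               class = "capacity_error")
})

test_that("no-signal data give chance AUC and strong niches are learned", {
  set.seed(71)
  # no signal: presences are uniform draws from the background distribution
  bg <- cbind(runif(3000, -3, 3), runif(3000, -3, 3))
  pres <- cbind(runif(400, -3, 3), runif(400, -3, 3))
  m0 <- fit_presence_background(pres[1:300, ], bg[1:2500, ])
  ho <- c(predict(m0, pres[301:400, ]), predict(m0, bg[2501:3000, ]))
  auc0 <- roc_auc(ho, c(rep(1, 100), rep(0, 500)))
  expect_equal(auc0, 0.5, tolerance = 0.05)

  # strong signal
  ns <- niche_sample(400, n_bg = 3000, opt = c(0.8, -0.5), sdev = c(0.4, 0.4))
  m1 <- fit_presence_background(ns$presences[1:300, ], ns$background[1:2500, ])
  ho1 <- c(predict(m1, ns$presences[301:400, ]),
           predict(m1, ns$background[2501:3000, ]))
  expect_gt(roc_auc(ho1, c(rep(1, 100), rep(0, 500))), 0.9)

  # presence centroid outranks the background median for a strong fit
  ctr <- matrix(colMeans(ns$presences[1:300, ]), 1)
  expect_gte(predict(m1, ctr), median(predict(m1, ns$background[1:2500, ])))
})

test_that("the optimizer is monotone, converges, and matches glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(72)
  ns <- niche_sample(250, n_bg = 1500)
  m <- fit_presence_background(ns$presences, ns$background)
  expect_true(m$training_meta$converged)
  expect_true(all(diff(m$objective_trace) <= 1e-12))

  # independent fit of the same weighted penalized objective
  feats <- disjunctSDM:::sdm_feature_matrix(
    rbind(ns$presences, ns$background), m$feature_spec)
  Fs <- scale(feats, center = m$center, scale = m$scale)
  y <- c(rep(1, nrow(ns$presences)), rep(0, nrow(ns$background)))
  w <- c(rep(1 / nrow(ns$presences), nrow(ns$presences)),
         rep(1 / nrow(ns$background), nrow(ns$background)))
  # glmnet rescales weights to sum to nobs and divides the loss by nobs;
  # our objective keeps class totals at 1 each, hence lambda = l1 / sum(w)
  g <- glmnet::glmnet(Fs, y, family = "binomial", weights = w,
                      lambda = m$l1 / sum(w), standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(m$coefficients),
               as.numeric(glmnet::coef.glmnet(g)), tolerance = 1e-3)
})

test_that("penalty limit shrinks to an intercept-only model; cap is flagged", {
  set.seed(73)
  ns <- niche_sample(100, n_bg = 600)
  m <- fit_presence_background(ns$presences, ns$background, l1 = 100)
  expect_true(all(abs(m$coefficients[-1]) < 1e-12))
  pred <- predict(m, ns$background[1:50, ])
  expect_lt(diff(range(pred)), 1e-12)

  capped <- fit_presence_background(ns$presences, ns$background,
                                    max_iter = 2, l1 = 0)
  expect_false(capped$training_meta$converged)
  expect_error(fit_presence_background(ns$presences[1:5, ], ns$background),
               class = "too_few_points")
})

test_that("suitability prediction respects the link, mask and feature contract", {
  pr <- test_projection()
  fx <- test_landscape()
  occ_sc <- project_points(pr, fx$stack, fx$occ$x, fx$occ$y)
  pa <- sample_pseudoabsences(fx$stack, 2000, seed = 5)
  bg_sc <- project_points(pr, fx$stack, pa$x, pa$y)
  m <- fit_presence_background(occ_sc, bg_sc)
  sm <- predict_suitability(m, pr, "current")
  expect_true(all(sm$values >= 0 & sm$values <= 1, na.rm = TRUE))
  expect_identical(is.na(sm$values), fx$stack$nodata |
                     is.na(pr$scores$current$PC1))

  # all-zero coefficients -> constant map at plogis(intercept)
  m0 <- m; m0$coefficients[] <- 0; m0$coefficients[1] <- 0.7
  sm0 <- predict_suitability(m0, pr, "current")
  expect_equal(unique(as.vector(sm0$values[!is.na(sm0$values)])), plogis(0.7))

  # monotone link: ordering of linear predictor preserved in suitability
  eta <- disjunctSDM:::sdm_eta(m, bg_sc)
  expect_identical(order(eta), order(predict(m, bg_sc)))

  expect_error(predict_suitability(m, pr, "nope"), class = "unknown_scenario")
})

test_that("implied optimum recovers a log-quadratic truth", {
  set.seed(74)
  ns <- niche_sample(500, n_bg = 4000, opt = c(0.8, -0.5), sdev = c(0.5, 0.5))
  m <- fit_presence_background(ns$presences, ns$background)
  opt <- implied_optimum(m)
  expect_lt(abs(opt[1] - 0.8), 0.3 * 0.5)
  expect_lt(abs(opt[2] + 0.5), 0.3 * 0.5)
})

test_that("cross-validation partitions presences and is reproducible", {
  set.seed(75)
  ns <- niche_sample(100, n_bg = 1000)
  cv <- cross_validate(ns$presences, ns$background, n_rep = 10,
                       test_frac = 0.3, seed = 4)
  expect_length(cv, 10)
  for (r in cv) {
    expect_equal(nrow(r$test_presences), 30)
    expect_equal(r$model$training_meta$n_presence, 70)
    # held-out indices are a strict subset; train + test partition the set
    expect_length(r$test_idx, 30)
    expect_false(anyDuplicated(r$test_idx) > 0)
    expect_setequal(c(r$test_idx, setdiff(seq_len(100), r$test_idx)),
                    seq_len(100))
  }
  cv2 <- cross_validate(ns$presences, ns$background, n_rep = 10,
                        test_frac = 0.3, seed = 4)
  expect_identical(cv[[3]]$test_presences, cv2[[3]]$test_presences)
  expect_identical(cv[[3]]$model$coefficients, cv2[[3]]$model$coefficients)

  expect_error(cross_validate(ns$presences[1:12, ], ns$background, n_rep = 2,
                              test_frac = 0.3, seed = 1),
               class = "too_few_points")
})
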