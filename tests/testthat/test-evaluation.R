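test_that("rank AUC equals the pairwise brute force and known cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_error(roc_auc(c(1, 2), c(1, 1)), class = "single_class")

  set.seed(81)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    sc <- sample(round(runif(n), sample(1:3, 1)))  # induces ties
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_equal(roc_auc(sc, lb), auc_bruteforce(sc, lb), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  skip_if_not_installed("pROC")
  set.seed(82)
  sc <- runif(150); lb <- rbinom(150, 1, 0.5)
  a <- roc_auc(sc, lb)
  expect_equal(roc_auc(qlogis(sc), lb), a, tolerance = 1e-12)
  expect_equal(roc_auc(sc^3 + 2 * sc, lb), a, tolerance = 1e-12)
  # independent implementation agrees
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                 direction = "<"))),
               tolerance = 1e-12)
})

test_that("TSS follows sensitivity + specificity - 1", {
  expect_equal(tss(10, 0, 10, 0), 1)
  expect_equal(tss(8, 3, 7, 2), 0.5)
  # prediction independent of truth: sens = 1 - spec -> 0
  expect_equal(tss(6, 6, 4, 4), 0)
  expect_error(tss(0, 3, 7, 0), class = "single_class")
})

test_that("all three threshold rules match the exhaustive-scan oracle", {
  set.seed(83)
  for (i in 1:100) {
    n <- sample(10:120, 1)
    sc <- round(runif(n), sample(1:3, 1))
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) == 0 || sum(lb) == n) next
    for (rule in c("SensEqSpec", "MaxSensSpec", "MinROCdist")) {
      got <- select_threshold(sc, lb, rule)
      want <- threshold_bruteforce(sc, lb, rule)
      # sentinel winners are reported as the equivalent finite cutoff
      if (want == -Inf) want <- min(sc)
      if (want == Inf) want <- max(sc) + 1
      expect_equal(got, want)
    }
  }
})

test_that("threshold selection handles separation and the stated example", {
  # perfectly separated: all rules cut between the classes
  sc <- c(0.1, 0.2, 0.8, 0.9); lb <- c(0, 0, 1, 1)
  for (rule in c("SensEqSpec", "MaxSensSpec", "MinROCdist")) {
    t <- select_threshold(sc, lb, rule)
    expect_true(t > 0.2 && t <= 0.8)
    expect_equal(mean(sc[lb == 1] >= t), 1)
    expect_equal(mean(sc[lb == 0] < t), 1)
  }
  t2 <- select_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1), "MaxSensSpec")
  expect_true(t2 > 0.4 && t2 <= 0.6)
})

test_that("max TSS over cutoffs is attained at the MaxSensSpec threshold", {
  set.seed(84)
  sc <- runif(200); lb <- rbinom(200, 1, 0.5)
  thr <- select_threshold(sc, lb, "MaxSensSpec")
  tss_at <- function(t) {
    pred <- as.integer(sc >= t)
    tss(sum(pred & lb), sum(pred & !lb), sum(!pred & !lb), sum(!pred & lb))
  }
  best <- max(vapply(unique(sc), tss_at, numeric(1)))
  expect_equal(tss_at(thr), best, tolerance = 1e-12)
})

test_that("binarization is monotone in the threshold and preserves nodata", {
  vals <- matrix(runif(100), 10, 10)
  vals[1, 1:3] <- NA
  sm <- structure(list(scenario_id = "current", values = vals,
                       model_label = "m"), class = "suitability_map")
  b0 <- binarize(sm, 0)
  expect_true(all(b0$values[!is.na(vals)] == 1))
  bhi <- binarize(sm, 2)
  expect_true(all(bhi$values[!is.na(vals)] == 0))
  expect_true(all(is.na(b0$values[1, 1:3])))
  t1 <- binarize(sm, 0.3)$values; t2 <- binarize(sm, 0.6)$values
  expect_true(all(t2[!is.na(t2)] <= t1[!is.na(t1)]))
  expect_error(binarize(sm, Inf), class = "invalid_parameter")
})

test_that("model sensitivity counts occurrences on suitable cells", {
  st <- climate_stack(list(env1 = matrix(0, 10, 10)))
  v <- matrix(0, 10, 10); v[1:5, ] <- 1
  bin <- binary_from_matrix(v)
  occ <- occurrence_table("sp", rep("core", 4), x = c(1, 2, 3, 4) + 0.5,
                          y = c(1.5, 2.5, 3.5, 8.5))  # 3 of 4 in rows 1:5
  expect_equal(model_sensitivity(bin, occ, st), 75)
  all1 <- binary_from_matrix(matrix(1, 10, 10))
  expect_equal(model_sensitivity(all1, occ, st), 100)
  all0 <- binary_from_matrix(matrix(0, 10, 10))
  expect_equal(model_sensitivity(all0, occ, st), 0)
  expect_error(model_sensitivity(bin, occ[0, ], st), class = "empty_group")
})

test_that("cross-validation evaluation produces sane summaries and the aggregate mean", {
  set.seed(85)
  ns <- niche_sample(120, n_bg = 1200, sdev = c(0.35, 0.35))
  cv <- cross_validate(ns$presences, ns$background, n_rep = 4, seed = 6)
  ev <- evaluate_cv(cv, "core")
  expect_equal(nrow(ev$runs), 4)
  expect_true(all(ev$runs$AUC >= 0 & ev$runs$AUC <= 1))
  expect_true(all(ev$runs$TSS >= -1 & ev$runs$TSS <= 1))
  expect_true(all(ev$runs$sensitivity >= 0 & ev$runs$sensitivity <= 1))

  ev2 <- evaluate_cv(cv, "disjunct")
  agg <- aggregate_scores(ev, ev2)
  expect_equal(agg$runs$AUC, (ev$runs$AUC + ev2$runs$AUC) / 2)
  expect_equal(agg$summary$mean[agg$summary$metric == "TSS"],
               mean((ev$runs$TSS + ev2$runs$TSS) / 2))
})
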