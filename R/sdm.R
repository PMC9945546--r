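#' Sample pseudo-absence cells
#'
#' Draws `n` distinct non-masked cells uniformly at random from the stack
#' (10 000 by convention), to stand in for absence data in presence-only
#' modelling. Deterministic given `seed`.
#'
#' @param stack a [climate_stack()].
#' @param n number of pseudo-absences.
#' @param seed integer RNG seed.
#' @return data.frame with columns `row`, `col`, `x`, `y`.
#' @export
sample_pseudoabsences <- function(stack, n = 10000, seed = 1) {
  n <- check_scalar_count(n, "n")
  avail <- which(!stack$nodata)
  if (n > length(avail))
    stop_dsdm(sprintf(
      "requested %d pseudo-absences but only %d non-masked cells exist; reduce `n`",
      n, length(avail)), "capacity_error")
  sel <- if (n == length(avail)) avail
         else with_seed(seed, sample(avail, n, replace = FALSE))
  rc <- arrayInd(sel, dim(stack))
  xy <- cell_centers(stack, rc[, 1], rc[, 2])
  data.frame(row = rc[, 1], col = rc[, 2], x = xy$x, y = xy$y)
}

# Feature expansion over the two PC axes. Returned columns depend on the
# requested terms: linear (PC1, PC2), quadratic (PC1^2, PC2^2), product
# (PC1*PC2).
sdm_feature_matrix <- function(scores, feature_spec) {
  p1 <- scores[, 1]; p2 <- scores[, 2]
  cols <- list()
  if ("linear" %in% feature_spec) cols <- c(cols, list(PC1 = p1, PC2 = p2))
  if ("quadratic" %in% feature_spec)
    cols <- c(cols, list(PC1sq = p1^2, PC2sq = p2^2))
  if ("product" %in% feature_spec) cols <- c(cols, list(PC1xPC2 = p1 * p2))
  if (!length(cols)) stop_dsdm("empty feature specification", "invalid_parameter")
  do.call(cbind, cols)
}

# L1-penalized weighted logistic objective. Case weights normalize each
# class to total weight one (presence 1/n_pres, background 1/n_bg), so the
# fit is invariant to duplicating background points and the penalty weight
# is interpreted against the per-presence log-likelihood, the convention of
# maximum-entropy presence-background regularization.
pb_objective <- function(beta, X, y, w, l1) {
  eta <- drop(X %*% beta)
  # numerically stable -log lik: log(1 + exp(eta)) - y*eta
  nll <- sum(w * (ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) -
                    y * eta))
  nll + l1 * sum(abs(beta[-1]))
}

pb_gradient <- function(beta, X, y, w) {
  eta <- drop(X %*% beta)
  drop(crossprod(X, w * (plogis(eta) - y)))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a presence-background suitability model
#'
#' Maximum-entropy-style presence-background estimation in its penalized
#' GLM form: an L1-penalized logistic regression of presences (1) against
#' background points (0) on polynomial features of the two shared PC axes.
#' Features are standardized internally; coefficients are reported on the
#' standardized scale together with the standardization constants. The
#' optimizer is a monotone accelerated proximal-gradient method (MFISTA)
#' with a fixed Lipschitz step; the objective trace is recorded and is
#' non-increasing. Convergence is declared when the max-norm of the
#' penalized subgradient falls below `tol`; hitting `max_iter` first is
#' flagged (not silent) in `training_meta$converged`.
#'
#' @param presences,background PC score matrices (columns PC1, PC2).
#' @param feature_spec subset of `c("linear", "quadratic", "product")`.
#' @param l1 L1 penalty weight against the class-normalized log-likelihood;
#'   default `0.05 / sqrt(nrow(presences))`, the maximum-entropy default
#'   regularization scale for quadratic features: it vanishes with data and
#'   keeps coefficients finite at small sample sizes without the vertex
#'   shrinkage a heavier penalty would cause.
#' @param max_iter optimizer iteration cap.
#' @param tol subgradient max-norm tolerance.
#' @param label dataset label stored in `training_meta`.
#' @param seed recorded in `training_meta` (the fit itself is
#'   deterministic).
#' @return object of class `sdm_model`: `coefficients` (intercept first),
#'   `feature_spec`, `l1`, `center`/`scale` per feature, `objective_trace`,
#'   `training_meta`.
#' @export
fit_presence_background <- function(presences, background,
                                    feature_spec = c("linear", "quadratic",
                                                     "product"),
                                    l1 = NULL, max_iter = 5000, tol = 1e-6,
                                    label = "species", seed = NA) {
  presences <- as.matrix(presences)[, 1:2, drop = FALSE]
  background <- as.matrix(background)[, 1:2, drop = FALSE]
  presences <- presences[stats::complete.cases(presences), , drop = FALSE]
  background <- background[stats::complete.cases(background), , drop = FALSE]
  if (nrow(presences) < 10L)
    stop_dsdm("need at least 10 presences", "too_few_points")
  if (nrow(background) < nrow(presences))
    stop_dsdm("background must be at least as large as the presence set",
              "invalid_parameter")
  if (is.null(l1)) l1 <- 0.05 / sqrt(nrow(presences))
  feature_spec <- match.arg(feature_spec, c("linear", "quadratic", "product"),
                            several.ok = TRUE)
  Fraw <- rbind(sdm_feature_matrix(presences, feature_spec),
                sdm_feature_matrix(background, feature_spec))
  # class-weighted standardization, so duplicated points do not move the
  # feature scale
  w0 <- c(rep(1 / nrow(presences), nrow(presences)),
          rep(1 / nrow(background), nrow(background)))
  w0 <- w0 / sum(w0)
  ctr <- drop(crossprod(w0, Fraw))
  scl <- sqrt(drop(crossprod(w0, sweep(Fraw, 2, ctr)^2)))
  scl[scl == 0] <- 1
  X <- cbind(Intercept = 1, scale(Fraw, center = ctr, scale = scl))
  y <- c(rep(1, nrow(presences)), rep(0, nrow(background)))
  w <- c(rep(1 / nrow(presences), nrow(presences)),
         rep(1 / nrow(background), nrow(background)))
  p <- ncol(X)

  # Lipschitz constant of the weighted logistic gradient
  L <- max(eigen(crossprod(X * sqrt(w)) / 4, symmetric = TRUE,
                 only.values = TRUE)$values)
  step <- 1 / L
  prox <- function(b) c(b[1], soft_threshold(b[-1], step * l1))

  beta <- numeric(p)
  xk <- beta; yk <- beta; tk <- 1
  obj <- pb_objective(beta, X, y, w, l1)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    zk <- prox(yk - step * pb_gradient(yk, X, y, w))
    obj_z <- pb_objective(zk, X, y, w, l1)
    # monotone step: keep the better of the proximal point and the incumbent
    if (obj_z <= obj) { xnew <- zk; obj_new <- obj_z }
    else { xnew <- xk; obj_new <- obj }
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yk <- xnew + (tk / tnew) * (zk - xnew) + ((tk - 1) / tnew) * (xnew - xk)
    xk <- xnew; tk <- tnew; obj <- obj_new
    trace <- c(trace, obj)
    g <- pb_gradient(xk, X, y, w)
    sub <- abs(g[1])
    gs <- g[-1]; bs <- xk[-1]
    sub <- max(sub, abs(gs + l1 * sign(bs))[bs != 0],
               pmax(abs(gs[bs == 0]) - l1, 0))
    if (sub < tol) { converged <- TRUE; break }
  }
  structure(
    list(coefficients = setNames(xk, colnames(X)),
         feature_spec = feature_spec, l1 = l1,
         center = ctr, scale = scl, objective_trace = trace,
         training_meta = list(label = label, n_presence = nrow(presences),
                              n_background = nrow(background), seed = seed,
                              iterations = length(trace) - 1L,
                              converged = converged)),
    class = "sdm_model"
  )
}

#' @export
print.sdm_model <- function(x, ...) {
  m <- x$training_meta
  cat(sprintf("sdm_model '%s': %d presences vs %d background, l1 = %.4g, %d iterations (%s)\n",
              m$label, m$n_presence, m$n_background, x$l1, m$iterations,
              if (m$converged) "converged" else "iteration cap reached"))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Linear predictor of an sdm_model on a score matrix.
sdm_eta <- function(model, scores) {
  Fraw <- sdm_feature_matrix(as.matrix(scores)[, 1:2, drop = FALSE],
                             model$feature_spec)
  if (ncol(Fraw) != length(model$coefficients) - 1L)
    stop_dsdm("feature/score mismatch", "feature_mismatch")
  X <- cbind(1, scale(Fraw, center = model$center, scale = model$scale))
  drop(X %*% model$coefficients)
}

#' Predict a suitability map for one scenario
#'
#' Applies the fitted model to the scenario's PC score grids and maps the
#' linear predictor through the logistic link to `[0, 1]`. Masked cells
#' propagate as `NA`. All binarization thresholds downstream are rank-based,
#' so the choice of monotone output link does not affect binary maps.
#'
#' @param model an [fit_presence_background()] result.
#' @param projection an [pooled_pca()] result.
#' @param scenario_id scenario whose score grids to use.
#' @return object of class `suitability_map`: `scenario_id`, `values`
#'   (matrix in `[0, 1]`, `NA` = nodata), `model_label`.
#' @export
predict_suitability <- function(model, projection, scenario_id = "current") {
  sc <- projection$scores[[scenario_id]]
  if (is.null(sc)) stop_dsdm(paste0("unknown scenario: ", scenario_id),
                             "unknown_scenario")
  d <- dim(sc$PC1)
  valid <- !is.na(sc$PC1)
  scores <- cbind(sc$PC1[valid], sc$PC2[valid])
  vals <- matrix(NA_real_, d[1], d[2])
  vals[valid] <- plogis(sdm_eta(model, scores))
  structure(list(scenario_id = scenario_id, values = vals,
                 model_label = model$training_meta$label),
            class = "suitability_map")
}

#' Predict suitability at points
#'
#' @param object an `sdm_model`.
#' @param scores matrix of PC scores.
#' @param ... unused.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.sdm_model <- function(object, scores, ...) plogis(sdm_eta(object, scores))

#' Implied niche optimum of a quadratic fit
#'
#' For a model with linear and quadratic (and optionally product) features,
#' the stationary point of the fitted quadratic form in PC space. Meaningful
#' when the quadratic is concave (a fitted niche mode).
#'
#' @param model an [fit_presence_background()] result fitted with at least
#'   linear and quadratic features.
#' @return numeric length-2 `(PC1, PC2)` of the stationary point.
#' @export
implied_optimum <- function(model) {
  if (!all(c("linear", "quadratic") %in% model$feature_spec))
    stop_dsdm("optimum requires linear and quadratic features",
              "invalid_parameter")
  # coefficients on the standardized scale -> map back to raw PC units
  b <- model$coefficients
  raw <- b[-1] / model$scale
  a1 <- raw["PC1"]; a2 <- raw["PC2"]
  b1 <- raw["PC1sq"]; b2 <- raw["PC2sq"]
  cc <- if ("PC1xPC2" %in% names(raw)) raw["PC1xPC2"] else 0
  H <- matrix(c(2 * b1, cc, cc, 2 * b2), 2, 2)
  if (abs(det(H)) < 1e-12)
    stop_dsdm("quadratic form is degenerate; optimum undefined", "degenerate")
  drop(solve(H, -c(a1, a2)))
}

#' Repeated split-sample cross-validation
#'
#' Repeats a random 70/30 (by default) presence split `n_rep` times, splits
#' the background alongside, fits one model per repetition on the training
#' portion, and reserves the held-out presences and background for
#' evaluation.
#'
#' @param presences,background PC score matrices.
#' @param n_rep number of repetitions (default 10).
#' @param test_frac held-out fraction (default 0.3).
#' @param seed integer RNG seed.
#' @param ... passed to [fit_presence_background()].
#' @return list of class `sdm_cv`; each element has `model`, `test_presences`,
#'   `test_background`, `split_id`.
#' @export
cross_validate <- function(presences, background, n_rep = 10, test_frac = 0.3,
                           seed = 1, ...) {
  n_rep <- check_scalar_count(n_rep, "n_rep", min = 1)
  if (test_frac <= 0 || test_frac >= 1)
    stop_dsdm("`test_frac` must be in (0, 1)", "invalid_parameter")
  presences <- as.matrix(presences)[, 1:2, drop = FALSE]
  background <- as.matrix(background)[, 1:2, drop = FALSE]
  presences <- presences[stats::complete.cases(presences), , drop = FALSE]
  np <- nrow(presences)
  n_test <- round(test_frac * np)
  if (np - n_test < 10L)
    stop_dsdm(sprintf(
      "too few presences: %d leave fewer than 10 training points at test_frac %.2f",
      np, test_frac), "too_few_points")
  nb <- nrow(background)
  nb_test <- round(test_frac * nb)
  runs <- with_seed(seed, lapply(seq_len(n_rep), function(r) {
    ip <- sample.int(np, n_test)
    ib <- sample.int(nb, nb_test)
    list(split_id = r, test_idx = sort(ip),
         train_presences = presences[-ip, , drop = FALSE],
         test_presences = presences[ip, , drop = FALSE],
         train_background = background[-ib, , drop = FALSE],
         test_background = background[ib, , drop = FALSE])
  }))
  out <- lapply(runs, function(r) {
    m <- fit_presence_background(r$train_presences, r$train_background,
                                 seed = seed, ...)
    m$training_meta$cv_split <- r$split_id
    list(model = m, test_presences = r$test_presences,
         test_background = r$test_background, split_id = r$split_id,
         test_idx = r$test_idx)
  })
  class(out) <- c("sdm_cv", "list")
  out
}
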