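#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks: the probability that a
#' randomly chosen presence scores higher than a randomly chosen background
#' point, with ties counting one half. Equal to the brute-force fraction of
#' winning presence-background pairs.
#'
#' @param scores predicted values.
#' @param labels 0/1 (or logical) indicator, 1 = presence.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop_dsdm("`scores` and `labels` differ in length", "invalid_parameter")
  np <- sum(labels == 1L); nb <- sum(labels == 0L)
  if (np == 0L || nb == 0L)
    stop_dsdm("both classes must be present", "single_class")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nb)
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1` from a confusion count.
#'
#' @param tp,fp,tn,fn confusion counts (true/false positive/negative).
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(tp, fp, tn, fn) {
  if (tp + fn == 0 || tn + fp == 0)
    stop_dsdm("both observed classes must be non-empty", "single_class")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# sensitivity/specificity of the classifier "score >= threshold" at each
# candidate threshold. Candidates are the unique scores plus -Inf/+Inf
# sentinels (predict-all and predict-none).
threshold_candidates <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  pres <- scores[labels == 1L]; bg <- scores[labels == 0L]
  if (!length(pres) || !length(bg))
    stop_dsdm("both classes must be present", "single_class")
  cand <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(cand, function(t) mean(pres >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(bg < t), numeric(1))
  list(threshold = cand, sens = sens, spec = spec)
}

#' Select a binarization threshold
#'
#' Scans every candidate cutoff (the unique score values plus sentinels) and
#' returns the one optimizing the requested rule:
#' * `SensEqSpec` — minimize `|sensitivity - specificity|`;
#' * `MaxSensSpec` — maximize `sensitivity + specificity`;
#' * `MinROCdist` — minimize the Euclidean distance of the ROC point to the
#'   ideal corner, `sqrt((1 - sens)^2 + (1 - spec)^2)`.
#' Ties break toward the lower threshold (higher sensitivity).
#'
#' @param scores predicted values.
#' @param labels 0/1 presence indicator.
#' @param rule one of `"SensEqSpec"`, `"MaxSensSpec"`, `"MinROCdist"`.
#' @return the selected threshold (cells with `score >= threshold` are
#'   classified suitable).
#' @export
select_threshold <- function(scores, labels,
                             rule = c("SensEqSpec", "MaxSensSpec",
                                      "MinROCdist")) {
  rule <- match.arg(rule)
  cand <- threshold_candidates(scores, labels)
  crit <- switch(rule,
    SensEqSpec = abs(cand$sens - cand$spec),
    MaxSensSpec = -(cand$sens + cand$spec),
    MinROCdist = sqrt((1 - cand$sens)^2 + (1 - cand$spec)^2))
  t <- cand$threshold[which.min(crit)]  # which.min takes the first = lowest cutoff
  # Sentinel winners classify identically to a finite cutoff; return that one
  # so downstream binarization always receives a finite threshold.
  if (t == -Inf) t <- min(scores)
  if (t == Inf) t <- max(scores) + 1
  t
}

#' Binarize a suitability map
#'
#' @param map a [predict_suitability()] result.
#' @param threshold_value finite cutoff; cells with suitability `>=` the
#'   cutoff become 1.
#' @param threshold_rule label recording how the cutoff was chosen.
#' @return object of class `binary_map`: `scenario_id`, `values` (0/1 with
#'   `NA` nodata), `threshold_rule`, `threshold_value`.
#' @export
binarize <- function(map, threshold_value, threshold_rule = "manual") {
  stopifnot(inherits(map, "suitability_map"))
  if (!is.finite(threshold_value))
    stop_dsdm("threshold must be finite", "invalid_parameter")
  vals <- ifelse(is.na(map$values), NA_real_,
                 as.numeric(map$values >= threshold_value))
  structure(list(scenario_id = map$scenario_id, values = vals,
                 threshold_rule = threshold_rule,
                 threshold_value = threshold_value),
            class = "binary_map")
}

#' Model sensitivity against occurrences
#'
#' Proportion of occupied sites correctly predicted suitable by a binary
#' map under current climate, as a percentage.
#'
#' @param binary a [binarize()] (or consensus) result.
#' @param occ an [occurrence_table()].
#' @param stack the [climate_stack()] providing grid geometry.
#' @return percentage in `[0, 100]`.
#' @export
model_sensitivity <- function(binary, occ, stack) {
  if (nrow(occ) == 0L)
    stop_dsdm("sensitivity is undefined for an empty occurrence set",
              "empty_group")
  rc <- point_cells(stack, occ$x, occ$y)
  if (anyNA(rc$row))
    stop_dsdm("occurrence(s) fall outside the raster extent", "off_grid")
  v <- binary$values[cbind(rc$row, rc$col)]
  100 * mean(v == 1, na.rm = FALSE)
}

#' Evaluate cross-validation runs
#'
#' For each run, predicts the held-out presences and background, computes
#' the rank AUC, selects the `MaxSensSpec` threshold on the held-out data
#' and reports TSS, sensitivity and specificity at that cutoff (so the TSS
#' is the maximum achievable on the evaluation data, the convention of
#' ensemble SDM platforms).
#'
#' @param cv an [cross_validate()] result.
#' @param model_type label (`"species"`, `"core"`, `"disjunct"`).
#' @return object of class `eval_scores`: data.frame `runs` (per-run AUC,
#'   TSS, sensitivity, specificity) plus `summary` (mean and sd per metric)
#'   and `model_type`.
#' @export
evaluate_cv <- function(cv, model_type = "species") {
  runs <- lapply(cv, function(r) {
    sc <- c(predict(r$model, r$test_presences),
            predict(r$model, r$test_background))
    lb <- c(rep(1L, nrow(r$test_presences)), rep(0L, nrow(r$test_background)))
    auc <- roc_auc(sc, lb)
    thr <- select_threshold(sc, lb, "MaxSensSpec")
    pred <- as.integer(sc >= thr)
    tp <- sum(pred == 1 & lb == 1); fp <- sum(pred == 1 & lb == 0)
    tn <- sum(pred == 0 & lb == 0); fn <- sum(pred == 0 & lb == 1)
    data.frame(split_id = r$split_id, AUC = auc, TSS = tss(tp, fp, tn, fn),
               sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  })
  runs <- do.call(rbind, runs)
  summ <- data.frame(
    metric = c("AUC", "TSS", "sensitivity", "specificity"),
    mean = c(mean(runs$AUC), mean(runs$TSS), mean(runs$sensitivity),
             mean(runs$specificity)),
    sd = c(sd(runs$AUC), sd(runs$TSS), sd(runs$sensitivity),
           sd(runs$specificity)))
  structure(list(runs = runs, summary = summ, model_type = model_type),
            class = "eval_scores")
}

#' @export
print.eval_scores <- function(x, ...) {
  cat(sprintf("eval_scores '%s' over %d runs:\n", x$model_type, nrow(x$runs)))
  print(transform(x$summary, mean = round(mean, 3), sd = round(sd, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Aggregate-model evaluation scores
#'
#' The aggregate (union) model has no fitted scores of its own; its AUC and
#' TSS are the arithmetic means of the core and disjunct models' per-run
#' scores.
#'
#' @param core_eval,disjunct_eval [evaluate_cv()] results.
#' @return an `eval_scores` with `model_type = "aggregate"`.
#' @export
aggregate_scores <- function(core_eval, disjunct_eval) {
  stopifnot(inherits(core_eval, "eval_scores"),
            inherits(disjunct_eval, "eval_scores"))
  runs <- core_eval$runs
  for (m in c("AUC", "TSS", "sensitivity", "specificity"))
    runs[[m]] <- (core_eval$runs[[m]] + disjunct_eval$runs[[m]]) / 2
  summ <- data.frame(
    metric = c("AUC", "TSS", "sensitivity", "specificity"),
    mean = vapply(c("AUC", "TSS", "sensitivity", "specificity"),
                  function(m) mean(runs[[m]]), numeric(1)),
    sd = vapply(c("AUC", "TSS", "sensitivity", "specificity"),
                function(m) sd(runs[[m]]), numeric(1)))
  structure(list(runs = runs, summary = summ, model_type = "aggregate"),
            class = "eval_scores")
}
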