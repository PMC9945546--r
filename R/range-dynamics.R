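#' Aggregate (union) binary model
#'
#' Cellwise logical OR of the core-group and disjunct-group binary maps: a
#' cell is suitable for the aggregate model if either group's model predicts
#' it suitable. Nodata where either input is nodata.
#'
#' @param core_bin,disjunct_bin [binarize()] results on the same grid and
#'   scenario.
#' @return a `binary_map`.
#' @export
aggregate_union <- function(core_bin, disjunct_bin) {
  if (!identical(dim(core_bin$values), dim(disjunct_bin$values)))
    stop_dsdm("binary maps are on different grids", "grid_mismatch")
  if (!identical(core_bin$scenario_id, disjunct_bin$scenario_id))
    stop_dsdm("binary maps refer to different scenarios", "scenario_mismatch")
  v <- pmax(core_bin$values, disjunct_bin$values)  # NA propagates
  structure(list(scenario_id = core_bin$scenario_id, values = v,
                 threshold_rule = "aggregate_union",
                 threshold_value = NA_real_),
            class = "binary_map")
}

#' Majority-consensus ensemble of binary maps
#'
#' Per-cell vote fraction across member maps; the consensus map is 1 where
#' at least `fraction` of members vote suitable (majority rule at the
#' default 0.5).
#'
#' @param members non-empty list of `binary_map`s on one grid.
#' @param fraction consensus fraction in `(0, 1]`.
#' @param scenario_id label for the result (defaults to the first member's).
#' @return object of class `consensus_map`: `votes` (matrix in `[0, 1]`),
#'   `consensus` (a `binary_map`), `fraction`, `n_members`.
#' @export
consensus <- function(members, fraction = 0.5,
                      scenario_id = members[[1]]$scenario_id) {
  if (length(members) == 0L)
    stop_dsdm("consensus of an empty member list is undefined", "empty_ensemble")
  if (fraction <= 0 || fraction > 1)
    stop_dsdm("`fraction` must be in (0, 1]", "invalid_parameter")
  d <- dim(members[[1]]$values)
  for (m in members)
    if (!identical(dim(m$values), d))
      stop_dsdm("member maps are on different grids", "grid_mismatch")
  votes <- Reduce(`+`, lapply(members, `[[`, "values")) / length(members)
  cons <- structure(
    list(scenario_id = scenario_id,
         values = ifelse(is.na(votes), NA_real_,
                         as.numeric(votes >= fraction)),
         threshold_rule = sprintf("consensus>=%g", fraction),
         threshold_value = fraction),
    class = "binary_map")
  structure(list(scenario_id = scenario_id, votes = votes, consensus = cons,
                 fraction = fraction, n_members = length(members)),
            class = "consensus_map")
}

#' Range change between two binary maps
#'
#' `RC = 100 * (RG - RL) / CPR` on the jointly non-masked cells, where RG
#' (range gain) counts cells unsuitable now but suitable in the future, RL
#' (range loss) counts cells suitable now but unsuitable in the future, and
#' CPR (current potential range) counts currently suitable cells. RC is
#' bounded below by -100 (total loss) and unbounded above.
#'
#' @param current,future `binary_map`s on the same grid.
#' @param model_type,rcp_id labels carried on the result.
#' @return object of class `range_change_result`: `RG`, `RL`, `CPR`, `RC`
#'   plus the labels.
#' @export
range_change <- function(current, future, model_type = "species",
                         rcp_id = NA_character_) {
  if (!identical(dim(current$values), dim(future$values)))
    stop_dsdm("binary maps are on different grids", "grid_mismatch")
  ok <- !is.na(current$values) & !is.na(future$values)
  cur <- current$values[ok] == 1
  fut <- future$values[ok] == 1
  CPR <- sum(cur)
  if (CPR == 0)
    stop_dsdm("current potential range is empty; RC is undefined",
              "undefined_rc")
  RG <- sum(!cur & fut)
  RL <- sum(cur & !fut)
  structure(list(model_type = model_type, rcp_id = rcp_id,
                 RG = RG, RL = RL, CPR = CPR,
                 RC = 100 * (RG - RL) / CPR),
            class = "range_change_result")
}

#' @export
print.range_change_result <- function(x, ...) {
  cat(sprintf("range change [%s, %s]: RG %d, RL %d, CPR %d -> RC %.1f%%\n",
              x$model_type, x$rcp_id, x$RG, x$RL, x$CPR, x$RC))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects the analysis settings in one validated object. Defaults follow
#' the study design: three background buffers (5, 10, 15 km), 10 000
#' pseudo-absences, 10 split-sample cross-validation repetitions holding out
#' 30%, 100 similarity randomizations, all three threshold rules, and a 50%
#' majority consensus.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param buffers_km background buffer radii (km).
#' @param env_grid_R environmental-space grid resolution per axis.
#' @param n_background number of pseudo-absence points.
#' @param n_cv cross-validation repetitions.
#' @param n_pa_sets independent pseudo-absence sets; the CV is repeated for
#'   each, giving `n_pa_sets * n_cv` runs in total (default 1).
#' @param test_frac held-out fraction per CV split.
#' @param similarity_reps randomizations in the similarity test.
#' @param alpha significance level.
#' @param consensus_fraction ensemble consensus fraction.
#' @param threshold_rules subset of the three threshold rules.
#' @param thin_cell_km spatial-thinning cell size (km).
#' @param l1 SDM penalty; `NULL` = `1/sqrt(n_presence)` per fit.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, buffers_km = c(5, 10, 15),
                            env_grid_R = 100, n_background = 10000,
                            n_cv = 10, n_pa_sets = 1, test_frac = 0.3,
                            similarity_reps = 100, alpha = 0.05,
                            consensus_fraction = 0.5,
                            threshold_rules = c("SensEqSpec", "MaxSensSpec",
                                                "MinROCdist"),
                            thin_cell_km = 1, l1 = NULL) {
  check_scalar_count(env_grid_R, "env_grid_R", min = 10)
  check_scalar_count(n_background, "n_background", min = 1)
  check_scalar_count(n_cv, "n_cv", min = 1)
  check_scalar_count(n_pa_sets, "n_pa_sets", min = 1)
  check_scalar_count(similarity_reps, "similarity_reps", min = 19)
  if (test_frac <= 0 || test_frac >= 1)
    stop_dsdm("`test_frac` must be in (0, 1)", "invalid_parameter")
  if (consensus_fraction <= 0 || consensus_fraction > 1)
    stop_dsdm("`consensus_fraction` must be in (0, 1]", "invalid_parameter")
  if (any(buffers_km <= 0)) stop_dsdm("buffers must be positive", "invalid_parameter")
  threshold_rules <- match.arg(threshold_rules,
                               c("SensEqSpec", "MaxSensSpec", "MinROCdist"),
                               several.ok = TRUE)
  structure(list(seed = as.integer(seed), buffers_km = buffers_km,
                 env_grid_R = env_grid_R, n_background = n_background,
                 n_cv = n_cv, n_pa_sets = n_pa_sets, test_frac = test_frac,
                 similarity_reps = similarity_reps, alpha = alpha,
                 consensus_fraction = consensus_fraction,
                 threshold_rules = threshold_rules,
                 thin_cell_km = thin_cell_km, l1 = l1),
            class = "pipeline_config")
}

# CV runs for one dataset, pooled over pseudo-absence sets.
run_cv_for_dataset <- function(pres_scores, bg_sets, config, label) {
  runs <- list()
  for (s in seq_along(bg_sets)) {
    cv <- cross_validate(pres_scores, bg_sets[[s]], n_rep = config$n_cv,
                         test_frac = config$test_frac,
                         seed = stage_seed(config$seed,
                                           paste0("cv_", label, "_", s)),
                         l1 = config$l1, label = label)
    runs <- c(runs, cv)
  }
  class(runs) <- c("sdm_cv", "list")
  runs
}

# Binary maps of every run x rule for one scenario.
member_binaries <- function(cv, projection, scenario_id, rules) {
  out <- list()
  for (r in cv) {
    suit <- predict_suitability(r$model, projection, scenario_id)
    sc <- c(predict(r$model, r$test_presences),
            predict(r$model, r$test_background))
    lb <- c(rep(1L, nrow(r$test_presences)), rep(0L, nrow(r$test_background)))
    for (rule in rules) {
      thr <- select_threshold(sc, lb, rule)
      out[[length(out) + 1L]] <- binarize(suit, thr, rule)
    }
  }
  out
}

#' Run the full disjunct-population analysis for one species
#'
#' End-to-end orchestration: spatial thinning; pooled PCA harmonized over
#' current and future scenarios; niche overlap and similarity tests per
#' background buffer and direction; species / core / disjunct SDMs under
#' repeated split-sample cross-validation; per-run, per-rule binary maps
#' combined by majority consensus (current maps across runs x rules, future
#' maps additionally across the GCMs of each RCP); aggregate (union) maps;
#' model sensitivity against all occurrences; and the range-change index
#' per model type and RCP. Every random stage draws a sub-seed derived from
#' `config$seed`, echoed in the run log.
#'
#' @param scenarios a [scenario_set()].
#' @param occurrences an [occurrence_table()] (one species, both groups).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, result CSVs
#'   (`niche_overlap.csv`, `evaluation.csv`, `range_change.csv`) and a JSON
#'   run log are written there deterministically.
#' @return list with elements `occurrences` (thinned), `projection`,
#'   `niche` (overlap/similarity table), `evaluation` (per-model scores
#'   table), `sensitivity` (per-model percentages), `current_binary`,
#'   `future_binary` (per model type / RCP), `range_change` (table), and
#'   `log`.
#' @export
run_species_analysis <- function(scenarios, occurrences, config = pipeline_config(),
                                 out_dir = NULL) {
  stopifnot(inherits(scenarios, "scenario_set"),
            inherits(config, "pipeline_config"))
  stack <- scenarios$current
  species <- occurrences$species[1]

  occ <- thin_occurrences(occurrences, cell_km = config$thin_cell_km,
                          seed = stage_seed(config$seed, "thin"),
                          origin = stack$origin)
  core <- occ[occ$group == "core", , drop = FALSE]
  disj <- occ[occ$group == "disjunct", , drop = FALSE]
  if (nrow(core) == 0L || nrow(disj) == 0L)
    stop_dsdm("stage occurrence_prep: both groups need occurrences after thinning",
              "empty_group")

  projection <- pooled_pca(scenarios)

  niche <- niche_analysis(projection, stack, occ,
                          buffers_km = config$buffers_km,
                          reps = config$similarity_reps, alpha = config$alpha,
                          seed = config$seed, R = config$env_grid_R,
                          species = species)

  pa_sets <- lapply(seq_len(config$n_pa_sets), function(s) {
    pa <- sample_pseudoabsences(stack, config$n_background,
                                seed = stage_seed(config$seed,
                                                  paste0("pseudoabsence_", s)))
    project_points(projection, stack, pa$x, pa$y)
  })
  datasets <- list(
    species = project_points(projection, stack, occ$x, occ$y),
    core = project_points(projection, stack, core$x, core$y),
    disjunct = project_points(projection, stack, disj$x, disj$y))
  cvs <- lapply(names(datasets), function(lab)
    run_cv_for_dataset(datasets[[lab]], pa_sets, config, lab))
  names(cvs) <- names(datasets)

  evals <- lapply(names(cvs), function(lab) evaluate_cv(cvs[[lab]], lab))
  names(evals) <- names(cvs)
  evals$aggregate <- aggregate_scores(evals$core, evals$disjunct)

  rules <- config$threshold_rules
  current_members <- lapply(cvs, member_binaries, projection = projection,
                            scenario_id = "current", rules = rules)
  current_binary <- lapply(current_members, function(m)
    consensus(m, config$consensus_fraction, "current")$consensus)
  current_binary$aggregate <- aggregate_union(current_binary$core,
                                              current_binary$disjunct)

  rcps <- unique(scenarios$rcp)
  future_binary <- list()
  for (rcp in rcps) {
    ids <- names(scenarios$futures)[scenarios$rcp == rcp]
    for (lab in names(cvs)) {
      members <- unlist(lapply(ids, function(id)
        member_binaries(cvs[[lab]], projection, id, rules)), recursive = FALSE)
      future_binary[[rcp]][[lab]] <-
        consensus(members, config$consensus_fraction, rcp)$consensus
    }
    future_binary[[rcp]]$aggregate <-
      aggregate_union(future_binary[[rcp]]$core, future_binary[[rcp]]$disjunct)
  }

  model_types <- c("species", "core", "disjunct", "aggregate")
  sens <- vapply(model_types, function(lab)
    model_sensitivity(current_binary[[lab]], occ, stack), numeric(1))

  rc_rows <- list()
  for (rcp in rcps) for (lab in model_types) {
    rc <- range_change(current_binary[[lab]], future_binary[[rcp]][[lab]],
                       model_type = lab, rcp_id = rcp)
    rc_rows[[length(rc_rows) + 1L]] <- data.frame(
      species = species, model_type = lab, rcp = rcp,
      RG = rc$RG, RL = rc$RL, CPR = rc$CPR, RC = rc$RC)
  }
  rc_table <- do.call(rbind, rc_rows)

  eval_table <- do.call(rbind, lapply(model_types, function(lab) {
    s <- evals[[lab]]$summary
    data.frame(species = species, model_type = lab,
               AUC = s$mean[s$metric == "AUC"], AUC_sd = s$sd[s$metric == "AUC"],
               TSS = s$mean[s$metric == "TSS"], TSS_sd = s$sd[s$metric == "TSS"],
               sensitivity_pct = sens[[lab]])
  }))

  log <- list(species = species, config = unclass(config),
              n_occurrences = nrow(occurrences), n_thinned = nrow(occ),
              n_core = nrow(core), n_disjunct = nrow(disj),
              scenarios = names(scenarios$futures),
              explained_var = projection$explained_var[1:2],
              stage_seeds = list(
                thin = stage_seed(config$seed, "thin"),
                pseudoabsence = stage_seed(config$seed, "pseudoabsence_1"),
                cv_species = stage_seed(config$seed, "cv_species_1")))

  result <- list(occurrences = occ, projection = projection, niche = niche,
                 evaluation = eval_table, evals = evals, sensitivity = sens,
                 current_binary = current_binary, future_binary = future_binary,
                 range_change = rc_table, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(niche, file.path(out_dir, "niche_overlap.csv"), row.names = FALSE)
    write.csv(eval_table, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
    write.csv(rc_table, file.path(out_dir, "range_change.csv"), row.names = FALSE)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
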