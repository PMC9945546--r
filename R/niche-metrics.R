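#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum_ij |z1_ij - z2_ij|` over two normalized occupancy
#' surfaces on the same environmental grid. Ranges from 0 (no overlap,
#' disjoint niches) to 1 (identical niches); symmetric in its arguments.
#'
#' @param z1,z2 [occurrence_density()] results on the same [env_grid()].
#' @return object of class `overlap_result`: `D`, `group_pair`.
#' @export
schoener_d <- function(z1, z2) {
  stopifnot(inherits(z1, "niche_density"), inherits(z2, "niche_density"))
  if (!same_grid(z1$grid, z2$grid))
    stop_dsdm("densities are on different environmental grids", "grid_mismatch")
  D <- 1 - 0.5 * sum(abs(z1$z - z2$z))
  D <- min(max(D, 0), 1)  # guard float round-off at the boundaries
  structure(list(D = D, group_pair = c(z1$group, z2$group)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Schoener's D (%s vs %s) = %.4f\n",
              x$group_pair[1], x$group_pair[2], x$D))
  invisible(x)
}

#' Background-randomization niche similarity test
#'
#' Tests whether the observed overlap between the focal group's niche and
#' the other group's niche is higher ("more" similar) or lower ("less"
#' similar) than expected from the environments available to the other
#' group. Each replicate redraws as many points as the other group has
#' occurrences, uniformly without replacement from the other group's
#' background cells, rebuilds that group's occupancy surface, and records
#' its overlap with the (fixed) focal surface. One-sided p-values use the
#' `(count + 1) / (reps + 1)` randomization convention, so they are never
#' exactly zero.
#'
#' @param occ_focal,occ_other occurrence PC score matrices of the two groups.
#' @param bg_focal,bg_other background-cell PC score matrices of the two
#'   groups.
#' @param grid an [env_grid()]; defaults to a grid over the pooled
#'   backgrounds so both surfaces are comparable cell-by-cell.
#' @param reps number of randomizations (>= 19; the study design uses 100).
#' @param alpha significance level for the verdict (default 0.05).
#' @param seed integer RNG seed.
#' @param R grid resolution when `grid` is not supplied.
#' @param correct occupancy-correct densities (see [occurrence_density()]).
#' @param direction label recording which group was randomized.
#' @return object of class `similarity_result`: `observed_D`, `null_D`
#'   (length `reps`), `p_more`, `p_less`, `verdict` (`"more"`, `"less"` or
#'   `"ns"`), `alpha`, `direction`.
#' @export
similarity_test <- function(occ_focal, bg_focal, occ_other, bg_other,
                            grid = NULL, reps = 100, alpha = 0.05, seed = 1,
                            R = 100, correct = TRUE,
                            direction = "focal_vs_other") {
  reps <- check_scalar_count(reps, "reps", min = 19)
  occ_other <- as.matrix(occ_other)[, 1:2, drop = FALSE]
  bg_other <- as.matrix(bg_other)[, 1:2, drop = FALSE]
  bg_other <- bg_other[stats::complete.cases(bg_other), , drop = FALSE]
  n_other <- nrow(occ_other)
  if (nrow(bg_other) < n_other)
    stop_dsdm(sprintf(
      "cannot draw %d points from a background of %d cells without replacement",
      n_other, nrow(bg_other)), "capacity_error")
  if (is.null(grid)) grid <- env_grid(list(bg_focal, bg_other), R = R)
  z_focal <- occurrence_density(occ_focal, bg_focal, grid, correct = correct,
                                group = "focal")
  z_other <- occurrence_density(occ_other, bg_other, grid, correct = correct,
                                group = "other")
  observed <- schoener_d(z_focal, z_other)$D
  # Background density and bandwidth are properties of bg_other: compute the
  # null surfaces with the same bandwidth so replicates differ only in the
  # resampled points.
  bw <- z_other$bandwidth
  null_D <- with_seed(seed, vapply(seq_len(reps), function(r) {
    sim <- bg_other[sample.int(nrow(bg_other), n_other, replace = FALSE), ,
                    drop = FALSE]
    z_sim <- occurrence_density(sim, bg_other, grid, bandwidth = bw,
                                correct = correct, group = "sim")
    schoener_d(z_focal, z_sim)$D
  }, numeric(1)))
  p_more <- (sum(null_D >= observed) + 1) / (reps + 1)
  p_less <- (sum(null_D <= observed) + 1) / (reps + 1)
  verdict <- if (p_more <= alpha) "more" else if (p_less <= alpha) "less" else "ns"
  structure(list(observed_D = observed, null_D = null_D, p_more = p_more,
                 p_less = p_less, verdict = verdict, alpha = alpha,
                 direction = direction),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity test (%s): D = %.4f, p_more = %.3f, p_less = %.3f -> %s\n",
              x$direction, x$observed_D, x$p_more, x$p_less, x$verdict))
  invisible(x)
}

#' Niche overlap and similarity across buffers and directions
#'
#' Runs Schoener's D and the similarity test in both directions (core vs
#' disjunct and disjunct vs core) for each background buffer radius,
#' producing one row per buffer x direction.
#'
#' @param projection an [pooled_pca()] result.
#' @param stack the current [climate_stack()].
#' @param occ thinned [occurrence_table()] with both groups present.
#' @param buffers_km background buffer radii (default `c(5, 10, 15)`).
#' @param reps,alpha,seed,R,correct see [similarity_test()].
#' @param species label for the output table.
#' @return data.frame: `species, buffer_km, direction, D, p_more, p_less,
#'   verdict`.
#' @export
niche_analysis <- function(projection, stack, occ, buffers_km = c(5, 10, 15),
                           reps = 100, alpha = 0.05, seed = 1, R = 100,
                           correct = TRUE, species = occ$species[1]) {
  core <- occ[occ$group == "core", , drop = FALSE]
  disj <- occ[occ$group == "disjunct", , drop = FALSE]
  if (nrow(core) == 0L || nrow(disj) == 0L)
    stop_dsdm("both groups must have occurrences", "empty_group")
  sc_core <- project_points(projection, stack, core$x, core$y)
  sc_disj <- project_points(projection, stack, disj$x, disj$y)
  rows <- list()
  for (b in buffers_km) {
    bg_c <- background_scores(projection, build_background(core, stack, b))
    bg_d <- background_scores(projection, build_background(disj, stack, b))
    grid <- env_grid(list(bg_c, bg_d), R = R)
    for (dir in c("core_vs_disjunct", "disjunct_vs_core")) {
      focal_first <- dir == "core_vs_disjunct"
      res <- similarity_test(
        occ_focal = if (focal_first) sc_core else sc_disj,
        bg_focal = if (focal_first) bg_c else bg_d,
        occ_other = if (focal_first) sc_disj else sc_core,
        bg_other = if (focal_first) bg_d else bg_c,
        grid = grid, reps = reps, alpha = alpha,
        seed = stage_seed(seed, paste0("similarity_", b, "_", dir)),
        correct = correct, direction = dir)
      rows[[length(rows) + 1L]] <- data.frame(
        species = species, buffer_km = b, direction = dir,
        D = res$observed_D, p_more = res$p_more, p_less = res$p_less,
        verdict = res$verdict)
    }
  }
  do.call(rbind, rows)
}
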