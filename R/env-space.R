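#' Harmonized PCA across climate scenarios
#'
#' Pools the layer values of the current and every future stack (row-stacked
#' non-masked cells), standardizes each layer, runs a principal component
#' analysis on the pooled matrix, and projects each scenario back onto the
#' shared first two axes. Projecting all scenarios with one set of loadings
#' keeps the environmental space comparable between current and future
#' climates and avoids model-transfer artefacts.
#'
#' @param scenarios a [scenario_set()].
#' @param n_comp number of components to retain as score grids (default 2).
#' @return an object of class `env_projection`: `loadings` (layers x
#'   `n_comp`), `center`/`scale` per layer, `explained_var` (all
#'   components), and `scores` — one list per scenario id holding score
#'   matrices `PC1`, `PC2`, ... on the raster grid.
#' @export
pooled_pca <- function(scenarios, n_comp = 2) {
  stopifnot(inherits(scenarios, "scenario_set"))
  stacks <- c(list(current = scenarios$current), scenarios$futures)
  valid <- !scenarios$current$nodata
  if (sum(valid) < 3L)
    stop_dsdm("need at least 3 non-masked cells", "invalid_parameter")
  layer_names <- names(scenarios$current$layers)
  if (length(layer_names) < 2L)
    stop_dsdm("need at least 2 layers", "invalid_parameter")
  pooled <- do.call(rbind, lapply(stacks, function(s) {
    vapply(s$layers, function(m) m[valid], numeric(sum(valid)))
  }))
  sds <- apply(pooled, 2, sd)
  if (any(sds == 0))
    stop_dsdm(paste0("degenerate (constant) layer(s): ",
                     paste(layer_names[sds == 0], collapse = ", ")),
              "rank_deficient")
  pc <- prcomp(pooled, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  n_comp <- min(n_comp, ncol(pc$rotation))
  scores <- lapply(stacks, function(s) {
    vals <- vapply(s$layers, function(m) m[valid], numeric(sum(valid)))
    sc <- scale(vals, center = pc$center, scale = pc$scale) %*%
      pc$rotation[, seq_len(n_comp), drop = FALSE]
    out <- lapply(seq_len(n_comp), function(j) {
      g <- matrix(NA_real_, nrow(s$nodata), ncol(s$nodata))
      g[valid] <- sc[, j]
      g
    })
    names(out) <- paste0("PC", seq_len(n_comp))
    out
  })
  names(scores) <- vapply(stacks, function(s) s$scenario_id, character(1))
  structure(
    list(loadings = pc$rotation[, seq_len(n_comp), drop = FALSE],
         center = pc$center, scale = pc$scale,
         explained_var = ev, n_comp = n_comp, scores = scores),
    class = "env_projection"
  )
}

#' @export
print.env_projection <- function(x, ...) {
  cat(sprintf("env_projection: %d components over %d layers; PC1 %.1f%%, PC2 %.1f%% of variance; scenarios: %s\n",
              x$n_comp, nrow(x$loadings), 100 * x$explained_var[1],
              100 * x$explained_var[2], paste(names(x$scores), collapse = ", ")))
  invisible(x)
}

#' Scores of planar points in the shared environmental space
#'
#' Reads the PC score grids of one scenario at the cells containing the
#' points, so occurrences and background cells live in the same discretized
#' environmental space as the suitability models.
#'
#' @param projection an [pooled_pca()] result.
#' @param stack the [climate_stack()] the scenario scores refer to.
#' @param x,y planar coordinates (km).
#' @param scenario_id which scenario's score grids to read.
#' @return numeric matrix, one row per point, columns `PC1`, `PC2`, ...
#' @export
project_points <- function(projection, stack, x, y, scenario_id = "current") {
  sc <- projection$scores[[scenario_id]]
  if (is.null(sc)) stop_dsdm(paste0("unknown scenario: ", scenario_id),
                             "unknown_scenario")
  rc <- point_cells(stack, x, y)
  idx <- cbind(rc$row, rc$col)
  out <- vapply(sc, function(m) m[idx], numeric(length(x)))
  if (length(x) == 1L) out <- matrix(out, 1L, dimnames = list(NULL, names(sc)))
  out
}

#' Scores of a background mask's cells
#'
#' @param projection an [pooled_pca()] result.
#' @param background a [build_background()] mask.
#' @param scenario_id which scenario's score grids to read.
#' @return matrix with one row per background cell, columns `PC1`, `PC2`.
#' @export
background_scores <- function(projection, background, scenario_id = "current") {
  sc <- projection$scores[[scenario_id]]
  idx <- which(background$cells)
  out <- vapply(sc, function(m) m[idx], numeric(length(idx)))
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Regular grid over 2-D environmental space
#'
#' @param scores matrix or list of matrices of PC scores whose pooled range
#'   (plus `margin`) the grid must cover.
#' @param R cells per axis (>= 10; default 100, the convention of the
#'   occurrence-density niche framework).
#' @param margin fractional range expansion per side (default 0.05).
#' @return object of class `env_grid`: `xlim`, `ylim`, `R`, and the cell
#'   centre sequences `x`, `y`.
#' @export
env_grid <- function(scores, R = 100, margin = 0.05) {
  R <- check_scalar_count(R, "R", min = 10)
  if (!is.list(scores)) scores <- list(scores)
  all_sc <- do.call(rbind, lapply(scores, function(s) s[, 1:2, drop = FALSE]))
  all_sc <- all_sc[stats::complete.cases(all_sc), , drop = FALSE]
  rng <- apply(all_sc, 2, range)
  pad <- margin * (rng[2, ] - rng[1, ])
  pad[pad == 0] <- 1e-6
  xlim <- c(rng[1, 1] - pad[1], rng[2, 1] + pad[1])
  ylim <- c(rng[1, 2] - pad[2], rng[2, 2] + pad[2])
  structure(list(xlim = xlim, ylim = ylim, R = R,
                 x = seq(xlim[1], xlim[2], length.out = R),
                 y = seq(ylim[1], ylim[2], length.out = R)),
            class = "env_grid")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$xlim, b$xlim)) && isTRUE(all.equal(a$ylim, b$ylim)) &&
    a$R == b$R
}

# Gaussian product-kernel density of 2-D points evaluated on the grid's
# R x R cell centres. Returns a matrix indexed [x, y].
kde_on_grid <- function(pts, grid, bandwidth) {
  n <- nrow(pts)
  kx <- dnorm(outer(grid$x, pts[, 1], "-") / bandwidth[1]) / bandwidth[1]
  ky <- dnorm(outer(grid$y, pts[, 2], "-") / bandwidth[2]) / bandwidth[2]
  (kx %*% t(ky)) / n
}

#' Occurrence density in environmental space
#'
#' Gridded occupancy surface following the kernel-density niche framework:
#' Gaussian-kernel densities of the occurrences and of the available
#' environment (background cells) are estimated on an `R x R` grid in PC
#' space; occupancy is the ratio occurrence density / background density
#' wherever the background density exceeds a small support threshold
#' (`1e-12` of its maximum), zero outside that support, and is normalized to
#' sum to one. The background correction removes the imprint of environment
#' availability so densities of groups with different backgrounds are
#' comparable.
#'
#' @param occ_scores matrix of occurrence PC scores (>= 5 rows).
#' @param bg_scores matrix of background-cell PC scores (non-empty).
#' @param grid an [env_grid()].
#' @param bandwidth `"auto"` (Silverman's rule per axis on the background
#'   scores) or numeric length-2 kernel standard deviations.
#' @param correct logical; `FALSE` skips the availability correction and
#'   returns the raw occurrence density (still support-masked and
#'   normalized), for sensitivity analysis.
#' @param group label carried on the result.
#' @return object of class `niche_density`: `grid`, `z` (`R x R`, sums to
#'   1), `bandwidth`, `group`, `support` (logical matrix).
#' @export
occurrence_density <- function(occ_scores, bg_scores, grid,
                               bandwidth = "auto", correct = TRUE,
                               group = "occ") {
  occ_scores <- as.matrix(occ_scores)[, 1:2, drop = FALSE]
  bg_scores <- as.matrix(bg_scores)[, 1:2, drop = FALSE]
  occ_scores <- occ_scores[stats::complete.cases(occ_scores), , drop = FALSE]
  bg_scores <- bg_scores[stats::complete.cases(bg_scores), , drop = FALSE]
  if (nrow(occ_scores) < 5L)
    stop_dsdm("need at least 5 occurrence points", "too_few_points")
  if (nrow(bg_scores) == 0L)
    stop_dsdm("background is empty", "empty_background")
  inside <- occ_scores[, 1] >= grid$xlim[1] & occ_scores[, 1] <= grid$xlim[2] &
    occ_scores[, 2] >= grid$ylim[1] & occ_scores[, 2] <= grid$ylim[2]
  if (!any(inside))
    stop_dsdm("all occurrences fall outside the grid bounds", "off_grid")
  if (identical(bandwidth, "auto")) {
    bandwidth <- c(bw.nrd0(bg_scores[, 1]), bw.nrd0(bg_scores[, 2]))
  }
  if (any(bandwidth <= 0))
    stop_dsdm("bandwidths must be positive", "invalid_parameter")
  occ_d <- kde_on_grid(occ_scores, grid, bandwidth)
  bg_d <- kde_on_grid(bg_scores, grid, bandwidth)
  support <- bg_d > 1e-12 * max(bg_d)
  z <- if (correct) ifelse(support, occ_d / pmax(bg_d, 1e-300), 0)
       else ifelse(support, occ_d, 0)
  s <- sum(z)
  if (s <= 0) stop_dsdm("density is identically zero on the grid", "degenerate")
  structure(list(grid = grid, z = z / s, bandwidth = bandwidth,
                 group = group, support = support),
            class = "niche_density")
}

#' @export
print.niche_density <- function(x, ...) {
  cat(sprintf("niche_density '%s': %d x %d grid, bandwidth (%.3g, %.3g)\n",
              x$group, x$grid$R, x$grid$R, x$bandwidth[1], x$bandwidth[2]))
  invisible(x)
}

#' Plot a niche density with background-extent contours
#'
#' Shades the occupancy surface and overlays contours enclosing 100% (solid)
#' and 50% (dashed) of the available environmental space, i.e. the 1.0 and
#' 0.5 quantile contours of the background density.
#'
#' @param x a [occurrence_density()] result.
#' @param bg_scores background PC scores used for the extent contours
#'   (optional).
#' @param ... passed to [graphics::image()].
#' @export
plot.niche_density <- function(x, bg_scores = NULL, ...) {
  cols <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x$grid$x, x$grid$y, x$z, col = cols,
                  xlab = "PC1", ylab = "PC2", ...)
  if (!is.null(bg_scores)) {
    bg_d <- kde_on_grid(as.matrix(bg_scores)[, 1:2, drop = FALSE], x$grid,
                        x$bandwidth)
    ord <- sort(bg_d, decreasing = TRUE)
    cum <- cumsum(ord) / sum(ord)
    lev50 <- ord[which(cum >= 0.5)[1]]
    lev100 <- 1e-12 * max(bg_d)
    graphics::contour(x$grid$x, x$grid$y, bg_d, levels = lev100, lty = 1,
                      drawlabels = FALSE, add = TRUE)
    graphics::contour(x$grid$x, x$grid$y, bg_d, levels = lev50, lty = 2,
                      drawlabels = FALSE, add = TRUE)
  }
  invisible(x)
}
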