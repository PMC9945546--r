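#' Virtual species with a known climatic niche
#'
#' Defines the truth oracle for validation: a Gaussian niche in layer space
#' (suitability = product of per-layer Gaussian terms, in `[0, 1]` with value
#' 1 at the optimum) plus two geographically disjoint sampling regions, the
#' larger "core" and the smaller "disjunct" group, separated by a gap.
#'
#' @param stack a [climate_stack()] defining the landscape.
#' @param optimum named numeric vector of niche-centre values; names must be
#'   layer names of `stack`. Layers not named are unconstrained.
#' @param breadth named numeric vector of per-layer niche standard deviations
#'   (same names as `optimum`); `Inf` removes the constraint.
#' @param gap_km minimum east-west separation between the core and disjunct
#'   regions (default 30 km).
#' @param core_frac,disjunct_frac fractions of the grid width assigned to the
#'   western (core) and eastern (disjunct) region.
#' @param true_threshold suitability cutoff defining the true range, as a
#'   fraction of the maximum suitability on the landscape (default 0.5).
#' @return an object of class `virtual_truth` with elements `optimum`,
#'   `breadth`, `suitability` (matrix in `[0, 1]`), `region_masks` (named
#'   list of logical matrices `core`, `disjunct`), `true_threshold` (absolute
#'   cutoff) and `true_range` (logical matrix of the true suitable area).
#' @export
virtual_truth <- function(stack, optimum, breadth, gap_km = 30,
                          core_frac = 0.42, disjunct_frac = 0.28,
                          true_threshold = 0.5) {
  stopifnot(inherits(stack, "climate_stack"))
  if (is.null(names(optimum)) || !all(names(optimum) %in% names(stack$layers)))
    stop_dsdm("`optimum` must be named with layer names of `stack`",
              "unknown_layer")
  if (!identical(sort(names(optimum)), sort(names(breadth))))
    stop_dsdm("`optimum` and `breadth` must share names", "invalid_parameter")
  if (any(breadth <= 0)) stop_dsdm("breadths must be positive", "invalid_parameter")
  d <- dim(stack)
  suit <- matrix(1, d[1], d[2])
  for (nm in names(optimum)) {
    if (is.finite(breadth[[nm]]))
      suit <- suit * exp(-(stack$layers[[nm]] - optimum[[nm]])^2 /
                           (2 * breadth[[nm]]^2))
  }
  suit[stack$nodata] <- NA_real_

  width_km <- d[2] * stack$cell_km
  if (gap_km >= width_km * (1 - core_frac - disjunct_frac))
    stop_dsdm("grid too narrow for the requested regions and gap",
              "invalid_parameter")
  colx <- (seq_len(d[2]) - 0.5) * stack$cell_km  # centre x relative to origin
  core_cols <- colx < core_frac * width_km
  disj_cols <- colx > (1 - disjunct_frac) * width_km
  mk_region <- function(cols) {
    m <- matrix(rep(cols, each = d[1]), d[1], d[2])
    m & !stack$nodata
  }
  core <- mk_region(core_cols)
  disjunct <- mk_region(disj_cols)
  gap_actual <- (min(colx[disj_cols]) - max(colx[core_cols]))
  if (gap_actual < gap_km)
    stop_dsdm("regions closer than the requested gap", "invalid_parameter")

  thr <- true_threshold * max(suit, na.rm = TRUE)
  structure(
    list(optimum = optimum, breadth = breadth, suitability = suit,
         region_masks = list(core = core, disjunct = disjunct),
         gap_km = gap_km, true_threshold = thr,
         true_range = !is.na(suit) & suit >= thr),
    class = "virtual_truth"
  )
}

#' @export
print.virtual_truth <- function(x, ...) {
  cat(sprintf("virtual_truth: optimum on [%s]; %d core / %d disjunct region cells; true range %d cells\n",
              paste(names(x$optimum), collapse = ", "),
              sum(x$region_masks$core), sum(x$region_masks$disjunct),
              sum(x$true_range)))
  invisible(x)
}

#' Build an occurrence table
#'
#' @param species species label(s).
#' @param group group label(s), each `"core"` or `"disjunct"`.
#' @param x,y planar coordinates in km.
#' @return data.frame of class `occurrence_table` with columns
#'   `species, group, x, y`.
#' @export
occurrence_table <- function(species, group, x, y) {
  group <- as.character(group)
  bad <- !group %in% c("core", "disjunct")
  if (any(bad))
    stop_dsdm(sprintf("invalid group label(s): %s",
                      paste(unique(group[bad]), collapse = ", ")),
              "invalid_group")
  out <- data.frame(species = as.character(species), group = group,
                    x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Sample virtual-species occurrences
#'
#' Draws grid cells without replacement within each region mask with
#' probability proportional to true suitability, and places one occurrence at
#' each drawn cell centre. Deterministic given `seed`.
#'
#' @param truth a [virtual_truth()].
#' @param stack the [climate_stack()] the truth was built on.
#' @param n_core,n_disjunct occurrence counts per group.
#' @param seed integer RNG seed.
#' @param species species label for the records.
#' @return an [occurrence_table()] with `n_core + n_disjunct` rows.
#' @export
sample_occurrences <- function(truth, stack, n_core, n_disjunct, seed = 1,
                               species = "virtual") {
  stopifnot(inherits(truth, "virtual_truth"), inherits(stack, "climate_stack"))
  n_core <- check_scalar_count(n_core, "n_core")
  n_disjunct <- check_scalar_count(n_disjunct, "n_disjunct")
  draw <- function(mask, n, grp) {
    idx <- which(mask & !is.na(truth$suitability) & truth$suitability > 0)
    if (length(idx) < n)
      stop_dsdm(sprintf(
        "requested %d %s occurrences but only %d cells with positive suitability",
        n, grp, length(idx)), "capacity_error")
    if (n == 0L) return(NULL)
    sel <- sample(idx, n, replace = FALSE, prob = truth$suitability[idx])
    rc <- arrayInd(sel, dim(stack))
    xy <- cell_centers(stack, rc[, 1], rc[, 2])
    occurrence_table(species, grp, xy$x, xy$y)
  }
  with_seed(seed, {
    core <- draw(truth$region_masks$core, n_core, "core")
    disj <- draw(truth$region_masks$disjunct, n_disjunct, "disjunct")
    out <- rbind(core, disj)
    if (is.null(out)) out <- occurrence_table(character(), character(),
                                              numeric(), numeric())
    class(out) <- c("occurrence_table", "data.frame")
    out
  })
}

#' Additive shift scaling the true suitable area
#'
#' Searches for a uniform additive offset, applied to every layer in
#' `layers` simultaneously, such that the number of cells in the true range
#' equals `target_ratio` times the current count. Used to construct future
#' scenarios with a known-truth range change; shifting several layers
#' coherently emulates a warming-like change that moves the whole climate
#' manifold rather than one variable in isolation.
#'
#' @param truth a [virtual_truth()].
#' @param stack the current [climate_stack()].
#' @param layers layer name(s) to shift; at least one must be a constrained
#'   niche axis.
#' @param target_ratio desired future/current true-range cell ratio.
#' @param max_offset search bound, in units of the first constrained layer's
#'   niche breadth.
#' @return the offset (layer units) whose induced area ratio is closest to
#'   `target_ratio`, with the achieved ratio as attribute `"ratio"`.
#' @export
shift_for_area_ratio <- function(truth, stack, layers, target_ratio = 0.5,
                                 max_offset = 6) {
  bad <- setdiff(layers, names(stack$layers))
  if (length(bad))
    stop_dsdm(paste0("unknown layer(s): ", paste(bad, collapse = ", ")),
              "unknown_layer")
  constrained <- intersect(layers, names(truth$optimum))
  constrained <- constrained[is.finite(unlist(truth$breadth[constrained]))]
  if (!length(constrained))
    stop_dsdm("`layers` must include a constrained niche axis", "unknown_layer")
  cur_n <- sum(truth$true_range, na.rm = TRUE)
  if (cur_n == 0) stop_dsdm("true range is empty", "invalid_parameter")
  ratio_at <- function(off) {
    shifted <- stack
    for (ly in layers) shifted$layers[[ly]] <- stack$layers[[ly]] + off
    suit <- matrix(1, nrow(stack$nodata), ncol(stack$nodata))
    for (nm in names(truth$optimum)) {
      if (is.finite(truth$breadth[[nm]]))
        suit <- suit * exp(-(shifted$layers[[nm]] - truth$optimum[[nm]])^2 /
                             (2 * truth$breadth[[nm]]^2))
    }
    suit[stack$nodata] <- NA_real_
    sum(suit >= truth$true_threshold, na.rm = TRUE) / cur_n
  }
  # The count is a step function of the offset; scan a fine grid and refine.
  sdl <- truth$breadth[[constrained[1]]]
  offs <- seq(0, max_offset * sdl, length.out = 400)
  ratios <- vapply(offs, ratio_at, numeric(1))
  i <- which.min(abs(ratios - target_ratio))
  fine <- seq(max(0, offs[max(1, i - 1)]), offs[min(length(offs), i + 1)],
              length.out = 200)
  fr <- vapply(fine, ratio_at, numeric(1))
  j <- which.min(abs(fr - target_ratio))
  structure(fine[j], ratio = fr[j])
}
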