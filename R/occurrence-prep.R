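#' Spatial thinning: one occurrence per grid cell
#'
#' Retains at most one record per species per `cell_km` grid cell, choosing
#' the retained record uniformly at random within each cell. The thinning
#' lattice is anchored at `origin` so thinning and modelling share one grid.
#' Deterministic given `seed`; group labels are preserved.
#'
#' @param occ an [occurrence_table()].
#' @param cell_km thinning cell size in km.
#' @param seed integer RNG seed.
#' @param origin lattice anchor (x, y) in km.
#' @return a thinned [occurrence_table()].
#' @export
thin_occurrences <- function(occ, cell_km = 1, seed = 1, origin = c(0, 0)) {
  check_positive(cell_km, "cell_km")
  if (nrow(occ) == 0L) return(occ)
  cell_id <- paste(occ$species,
                   floor((occ$x - origin[1]) / cell_km),
                   floor((occ$y - origin[2]) / cell_km), sep = "|")
  keep <- with_seed(seed, {
    # uniform random representative per occupied cell
    vapply(split(seq_len(nrow(occ)), cell_id), function(idx) {
      if (length(idx) == 1L) idx else sample(idx, 1L)
    }, integer(1))
  })
  out <- occ[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Buffered background area around a group's occurrences
#'
#' A cell belongs to the background iff its centre lies within `buffer_km`
#' (planar distance) of at least one occurrence of the group and the cell is
#' not nodata.
#'
#' @param occ_group an [occurrence_table()] subset (one group), non-empty.
#' @param stack a [climate_stack()].
#' @param buffer_km buffer radius in km (the study design uses 5, 10, 15).
#' @param group label recorded on the result (`"core"`, `"disjunct"` or
#'   `"species"`).
#' @return an object of class `background_mask`: list with `group`,
#'   `buffer_km` and `cells` (logical matrix, `TRUE` = in background).
#' @export
build_background <- function(occ_group, stack, buffer_km,
                             group = occ_group$group[1]) {
  stopifnot(inherits(stack, "climate_stack"))
  check_positive(buffer_km, "buffer_km")
  if (nrow(occ_group) == 0L)
    stop_dsdm("background is undefined for an empty occurrence group",
              "empty_group")
  d <- dim(stack)
  cells <- matrix(FALSE, d[1], d[2])
  # visit only cells inside each occurrence's bounding box
  r_cells <- ceiling(buffer_km / stack$cell_km) + 1L
  rc_all <- point_cells(stack, occ_group$x, occ_group$y)
  if (anyNA(rc_all$row))
    stop_dsdm("occurrence(s) fall outside the raster extent", "off_grid")
  for (k in seq_len(nrow(occ_group))) {
    rc <- rc_all[k, ]
    rows <- max(1L, rc$row - r_cells):min(d[1], rc$row + r_cells)
    cols <- max(1L, rc$col - r_cells):min(d[2], rc$col + r_cells)
    cx <- stack$origin[1] + (cols - 0.5) * stack$cell_km
    cy <- stack$origin[2] + (rows - 0.5) * stack$cell_km
    dd <- outer((cy - occ_group$y[k])^2, (cx - occ_group$x[k])^2, "+")
    cells[rows, cols] <- cells[rows, cols] | (dd <= buffer_km^2)
  }
  cells <- cells & !stack$nodata
  structure(list(group = group, buffer_km = buffer_km, cells = cells),
            class = "background_mask")
}

#' @export
print.background_mask <- function(x, ...) {
  cat(sprintf("background_mask '%s', %g km buffer: %d cells\n",
              x$group, x$buffer_km, sum(x$cells)))
  invisible(x)
}

#' Union of background masks
#'
#' The species-level background is the union of the core and disjunct
#' backgrounds at the same radius.
#'
#' @param a,b [build_background()] results on the same grid.
#' @return a `background_mask` with `group = "species"`.
#' @export
union_background <- function(a, b) {
  if (!identical(dim(a$cells), dim(b$cells)) || a$buffer_km != b$buffer_km)
    stop_dsdm("backgrounds must share grid and buffer radius", "shape_mismatch")
  structure(list(group = "species", buffer_km = a$buffer_km,
                 cells = a$cells | b$cells),
            class = "background_mask")
}
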