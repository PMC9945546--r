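#' Climate raster stack
#'
#' A `climate_stack` holds named, co-registered raster layers for one climate
#' scenario on a regular planar grid. Cells are square with side `cell_km`
#' kilometres; the grid origin (`origin`) is the lower-left corner of cell
#' `[1, 1]`, so row 1 is the southernmost row and the centre of cell
#' `[i, j]` sits at `origin + (j - 0.5, i - 0.5) * cell_km`. All layers share
#' one shape and one nodata mask.
#'
#' @param layers named list of numeric matrices, all of identical dimension.
#' @param scenario_id text label, e.g. `"current"` or `"GCM1_rcp26"`.
#' @param origin numeric length-2, planar (x, y) of the grid's lower-left
#'   corner in km.
#' @param cell_km cell side length in km.
#' @param nodata optional logical matrix (`TRUE` = no data) of the same
#'   dimension as the layers; `NULL` means every cell is valid.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(layers, scenario_id = "current", origin = c(0, 0),
                          cell_km = 1, nodata = NULL) {
  if (!is.list(layers) || length(layers) == 0L)
    stop_dsdm("`layers` must be a non-empty named list of matrices",
              "invalid_parameter")
  nms <- names(layers)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
    stop_dsdm("layer names must be unique and non-empty", "invalid_parameter")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_dsdm("all layers must share the same dimensions", "shape_mismatch")
  check_positive(cell_km, "cell_km")
  dm <- dims[, 1]
  if (is.null(nodata)) nodata <- matrix(FALSE, dm[1], dm[2])
  if (!is.logical(nodata) || !identical(dim(nodata), dm))
    stop_dsdm("`nodata` must be a logical matrix matching the layers",
              "invalid_parameter")
  layers <- lapply(layers, function(m) {
    m[nodata] <- NA_real_
    if (any(!is.finite(m[!nodata])))
      stop_dsdm("non-masked cells must be finite", "invalid_value")
    m
  })
  structure(
    list(scenario_id = scenario_id, layers = layers,
         origin = as.numeric(origin[1:2]), cell_km = cell_km,
         nodata = nodata),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("climate_stack '%s': %d layer(s) [%s], %d x %d cells @ %g km, %d nodata\n",
              x$scenario_id, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              d[1], d[2], x$cell_km, sum(x$nodata)))
  invisible(x)
}

#' @export
dim.climate_stack <- function(x) dim(x$layers[[1]])

n_valid_cells <- function(stack) sum(!stack$nodata)

#' Planar coordinates of cell centres
#'
#' @param stack a [climate_stack()].
#' @param rows,cols integer vectors of equal length (recycled).
#' @return data.frame with columns `x`, `y` (km).
#' @export
cell_centers <- function(stack, rows, cols) {
  data.frame(x = stack$origin[1] + (cols - 0.5) * stack$cell_km,
             y = stack$origin[2] + (rows - 0.5) * stack$cell_km)
}

#' Map planar points to grid cells
#'
#' @param stack a [climate_stack()].
#' @param x,y planar coordinates in km.
#' @return data.frame with columns `row`, `col`; `NA` for points off-grid.
#' @export
point_cells <- function(stack, x, y) {
  d <- dim(stack)
  col <- floor((x - stack$origin[1]) / stack$cell_km) + 1L
  row <- floor((y - stack$origin[2]) / stack$cell_km) + 1L
  off <- row < 1L | row > d[1] | col < 1L | col > d[2]
  row[off] <- NA_integer_; col[off] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract layer values at planar points
#'
#' @inheritParams point_cells
#' @return numeric matrix, one row per point, one column per layer; rows are
#'   `NA` for points off-grid or on nodata cells.
#' @export
extract_values <- function(stack, x, y) {
  rc <- point_cells(stack, x, y)
  idx <- cbind(rc$row, rc$col)
  out <- vapply(stack$layers, function(m) m[idx], numeric(length(x)))
  if (length(x) == 1L) out <- matrix(out, 1L, dimnames = list(NULL, names(stack$layers)))
  out
}

# Separable Gaussian smoothing of a matrix with kernel sd `sigma` (cells),
# renormalized at the edges so smoothing preserves a constant field exactly.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  smooth_1d <- function(mat) {
    n <- nrow(mat)
    band <- matrix(0, n, n)
    for (off in seq(-r, r)) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1L & j <= n
      band[cbind(i[ok], j[ok])] <- k[off + r + 1L]
    }
    sw <- band %*% matrix(1, n, ncol(mat))  # row sums, edge renormalization
    (band %*% mat) / sw
  }
  t(smooth_1d(t(smooth_1d(m))))
}

#' Generate a synthetic climate stack
#'
#' Layers are smooth Gaussian random fields built by Gaussian-filtering white
#' noise (autocorrelation scale `autocorr_range` km) and mixing the fields to
#' a uniform pairwise cross-correlation `cross_corr`. Each layer is then
#' scaled to the requested mean and standard deviation. Deterministic given
#' `seed`.
#'
#' @param n_layers number of climate layers (>= 2).
#' @param shape integer `(rows, cols)` of the grid.
#' @param autocorr_range spatial autocorrelation scale in km (Gaussian kernel
#'   standard deviation).
#' @param cross_corr either a single target pairwise correlation between
#'   layers (a uniform, exchangeable structure; must keep that matrix
#'   positive definite, i.e. `cross_corr > -1/(n_layers - 1)`) or a full
#'   `n_layers x n_layers` correlation matrix, e.g. a block structure with a
#'   temperature-like and a precipitation-like variable group.
#' @param seed integer RNG seed.
#' @param cell_km cell size in km.
#' @param layer_means,layer_sds per-layer location/scale (recycled).
#' @param nodata optional logical nodata mask.
#' @return a [climate_stack()] with layers named `env1..envk`.
#' @export
generate_climate_stack <- function(n_layers, shape = c(200, 200),
                                   autocorr_range = 20, cross_corr = 0.3,
                                   seed = 1, cell_km = 1,
                                   layer_means = 0, layer_sds = 1,
                                   nodata = NULL) {
  n_layers <- check_scalar_count(n_layers, "n_layers", min = 2)
  if (length(shape) != 2L || any(shape < 2))
    stop_dsdm("`shape` must give positive (rows, cols)", "invalid_parameter")
  check_positive(autocorr_range, "autocorr_range")
  if (is.matrix(cross_corr)) {
    R <- cross_corr
    if (!identical(dim(R), c(n_layers, n_layers)) ||
        any(abs(R - t(R)) > 1e-12) || any(diag(R) != 1) ||
        min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop_dsdm("`cross_corr` matrix must be a valid correlation matrix",
                "invalid_parameter")
  } else {
    if (abs(cross_corr) > 1 || cross_corr <= -1 / (n_layers - 1))
      stop_dsdm("`cross_corr` does not define a valid correlation matrix",
                "invalid_parameter")
    R <- matrix(cross_corr, n_layers, n_layers)
    diag(R) <- 1
  }
  sigma <- autocorr_range / cell_km
  means <- rep_len(layer_means, n_layers)
  sds <- rep_len(layer_sds, n_layers)

  fields <- with_seed(seed, {
    lapply(seq_len(n_layers), function(i) {
      f <- gauss_smooth(matrix(rnorm(prod(shape)), shape[1], shape[2]), sigma)
      (f - mean(f)) / max(sd(f), .Machine$double.eps)
    })
  })
  # Mix standardized fields to the target correlation via Cholesky.
  L <- chol(R)
  flat <- vapply(fields, as.vector, numeric(prod(shape)))
  mixed <- flat %*% L
  layers <- lapply(seq_len(n_layers), function(i) {
    m <- matrix(mixed[, i], shape[1], shape[2])
    means[i] + sds[i] * m
  })
  names(layers) <- paste0("env", seq_len(n_layers))
  climate_stack(layers, scenario_id = "current", cell_km = cell_km,
                nodata = nodata)
}

#' Derive a future scenario from a current stack
#'
#' `future = factor * current + offset + smooth noise`, cellwise per layer,
#' with the nodata mask preserved. Offsets/factors default to identity for
#' layers not named in `shift`. The noise component is a smooth random field
#' (same construction as [generate_climate_stack()]) with standard deviation
#' `noise_sd`, emulating the spread between general circulation models.
#'
#' @param current a [climate_stack()].
#' @param shift named list; each element is `list(offset =, factor =)` for a
#'   layer of `current` (either component optional).
#' @param noise_sd standard deviation of the added smooth noise, in layer
#'   units (0 = deterministic shift).
#' @param seed integer RNG seed.
#' @param gcm,rcp labels recorded in the scenario id (`"<gcm>_<rcp>"`).
#' @param autocorr_range autocorrelation scale of the noise field, km.
#' @return a [climate_stack()] with `scenario_id = "<gcm>_<rcp>"`.
#' @export
generate_future_stack <- function(current, shift = list(), noise_sd = 0,
                                  seed = 1, gcm = "GCM1", rcp = "rcp26",
                                  autocorr_range = 20) {
  stopifnot(inherits(current, "climate_stack"))
  bad <- setdiff(names(shift), names(current$layers))
  if (length(bad))
    stop_dsdm(paste0("unknown layer(s) in `shift`: ", paste(bad, collapse = ", ")),
              "unknown_layer")
  shp <- dim(current)
  sigma <- autocorr_range / current$cell_km
  noise <- if (noise_sd > 0) {
    with_seed(seed, lapply(seq_along(current$layers), function(i) {
      f <- gauss_smooth(matrix(rnorm(prod(shp)), shp[1], shp[2]), sigma)
      noise_sd * (f - mean(f)) / max(sd(f), .Machine$double.eps)
    }))
  } else {
    rep(list(matrix(0, shp[1], shp[2])), length(current$layers))
  }
  layers <- lapply(seq_along(current$layers), function(i) {
    nm <- names(current$layers)[i]
    off <- shift[[nm]]$offset %||% 0
    fac <- shift[[nm]]$factor %||% 1
    fac * current$layers[[i]] + off + noise[[i]]
  })
  names(layers) <- names(current$layers)
  climate_stack(layers, scenario_id = paste(gcm, rcp, sep = "_"),
                origin = current$origin, cell_km = current$cell_km,
                nodata = current$nodata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle a current stack with its future scenarios
#'
#' @param current a [climate_stack()].
#' @param futures list of [climate_stack()]s; each must share grid geometry
#'   and layer names with `current`. Scenario ids of the form `"<gcm>_<rcp>"`
#'   are parsed into GCM and RCP labels.
#' @return an object of class `scenario_set`.
#' @export
scenario_set <- function(current, futures = list()) {
  stopifnot(inherits(current, "climate_stack"))
  for (f in futures) {
    stopifnot(inherits(f, "climate_stack"))
    if (!identical(dim(f), dim(current)) ||
        !identical(names(f$layers), names(current$layers)) ||
        !identical(f$nodata, current$nodata))
      stop_dsdm("future stacks must share grid, layer names and mask with current",
                "shape_mismatch")
  }
  ids <- vapply(futures, function(f) f$scenario_id, character(1))
  if (anyDuplicated(ids))
    stop_dsdm("future scenario ids must be unique", "invalid_parameter")
  names(futures) <- ids
  parts <- strsplit(ids, "_", fixed = TRUE)
  structure(
    list(current = current, futures = futures,
         gcm = vapply(parts, `[`, character(1), 1),
         rcp = vapply(parts, function(p) paste(p[-1], collapse = "_"), character(1))),
    class = "scenario_set"
  )
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("scenario_set: current + %d future(s) [%s]\n",
              length(x$futures), paste(names(x$futures), collapse = ", ")))
  invisible(x)
}
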