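#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text interchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, northernmost row first. Nodata cells are written as -9999.
#'
#' @param values numeric matrix (row 1 = southernmost row, the in-memory
#'   convention of [climate_stack()]).
#' @param path output file.
#' @param origin lower-left corner (x, y) in km.
#' @param cell_km cell size.
#' @param nodata_value sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(values, path, origin = c(0, 0), cell_km = 1,
                             nodata_value = -9999) {
  d <- dim(values)
  header <- c(
    sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", origin[1]), sprintf("yllcorner %.10g", origin[2]),
    sprintf("cellsize %.10g", cell_km), sprintf("NODATA_value %g", nodata_value))
  m <- values[rev(seq_len(d[1])), , drop = FALSE]  # north-up on disk
  m[is.na(m)] <- nodata_value
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return list with `values` (matrix, row 1 = south, `NA` = nodata),
#'   `origin`, `cell_km`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop_dsdm(paste0("malformed ASCII grid header in ", path), "io_error")
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  list(values = m[rev(seq_len(hdr$nrows)), , drop = FALSE],
       origin = c(hdr$xllcorner, hdr$yllcorner), cell_km = hdr$cellsize)
}

#' Write a climate stack to a directory
#'
#' One ASCII grid per layer (`<layer>.asc`) plus a JSON sidecar with the
#' scenario id and grid geometry.
#'
#' @param stack a [climate_stack()].
#' @param dir output directory (created if needed).
#' @export
write_climate_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers))
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     origin = stack$origin, cell_km = stack$cell_km)
  jsonlite::write_json(
    list(scenario_id = stack$scenario_id, layers = names(stack$layers),
         origin = stack$origin, cell_km = stack$cell_km),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read co-registered raster layers into a climate stack
#'
#' @param paths character vector of ASCII grid files, one per layer.
#' @param layer_names names for the layers (default: file base names).
#' @param scenario_id label for the stack.
#' @return a [climate_stack()]; the nodata mask is the union of the
#'   per-layer masks.
#' @export
read_raster_stack <- function(paths, layer_names = NULL,
                              scenario_id = "current") {
  if (is.null(layer_names))
    layer_names <- sub("\\.asc$", "", basename(paths))
  grids <- lapply(paths, read_ascii_grid)
  dims <- vapply(grids, function(g) dim(g$values), integer(2))
  geom <- vapply(grids, function(g) c(g$origin, g$cell_km), numeric(3))
  mism <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1] |
                  abs(geom[1, ] - geom[1, 1]) > 1e-9 |
                  abs(geom[2, ] - geom[2, 1]) > 1e-9 |
                  abs(geom[3, ] - geom[3, 1]) > 1e-9)
  if (length(mism))
    stop_dsdm(paste0("layer(s) not co-registered with the first: ",
                     paste(basename(paths[mism]), collapse = ", ")),
              "shape_mismatch")
  nodata <- Reduce(`|`, lapply(grids, function(g) is.na(g$values)))
  layers <- setNames(lapply(grids, `[[`, "values"), layer_names)
  climate_stack(layers, scenario_id = scenario_id,
                origin = grids[[1]]$origin, cell_km = grids[[1]]$cell_km,
                nodata = nodata)
}

#' Write a background mask as a 0/1 ASCII grid
#'
#' @param background a [build_background()] result.
#' @param path output file.
#' @param origin,cell_km grid geometry.
#' @export
write_background <- function(background, path, origin = c(0, 0), cell_km = 1) {
  write_ascii_grid(background$cells * 1, path, origin = origin,
                   cell_km = cell_km)
}

#' Write an occurrence table as CSV
#'
#' @param occ an [occurrence_table()].
#' @param path output file (header `species,group,x,y`).
#' @export
write_occurrences <- function(occ, path) {
  write.csv(occ[, c("species", "group", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence table from CSV
#'
#' Validates the schema and every row: the group label must be `core` or
#' `disjunct`, and coordinates must be finite. Offending rows are reported
#' by line number. When a `stack` is given, off-grid rows are rejected too.
#'
#' @param path CSV with header `species,group,x,y`.
#' @param stack optional [climate_stack()] for on-grid validation.
#' @return an [occurrence_table()].
#' @export
read_occurrences <- function(path, stack = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "group", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_dsdm(paste0("missing column(s): ", paste(miss, collapse = ", ")),
              "schema_error")
  bad_group <- !df$group %in% c("core", "disjunct")
  bad_xy <- !is.finite(df$x) | !is.finite(df$y)
  bad <- bad_group | bad_xy
  if (!is.null(stack)) {
    rc <- point_cells(stack, df$x, df$y)
    off <- is.na(rc$row)
    off[bad_xy] <- FALSE
    bad <- bad | off
  }
  if (any(bad))
    stop_dsdm(sprintf("invalid occurrence row(s) at line(s): %s",
                      paste(which(bad) + 1L, collapse = ", ")),
              "invalid_rows")
  occurrence_table(df$species, df$group, df$x, df$y)
}

#' Write a virtual-truth sidecar
#'
#' Serializes the truth parameters (optimum, breadth, threshold) as JSON so
#' an analysis on synthetic data can be audited against its generating
#' niche. Grids are not serialized; rebuild them with [virtual_truth()].
#'
#' @param truth a [virtual_truth()].
#' @param path output JSON file.
#' @export
write_virtual_truth <- function(truth, path) {
  jsonlite::write_json(
    list(optimum = as.list(truth$optimum), breadth = as.list(truth$breadth),
         gap_km = truth$gap_km, true_threshold = truth$true_threshold,
         true_range_cells = sum(truth$true_range, na.rm = TRUE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a niche density as CSV plus JSON metadata
#'
#' The occupancy matrix is written as a plain CSV (rows = PC1 grid cells,
#' columns = PC2 grid cells) with a JSON sidecar recording the grid bounds,
#' resolution, bandwidth and group label.
#'
#' @param density a [occurrence_density()] result.
#' @param path output CSV file; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_niche_density <- function(density, path) {
  stopifnot(inherits(density, "niche_density"))
  utils::write.table(density$z, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(group = density$group, R = density$grid$R,
         xlim = density$grid$xlim, ylim = density$grid$ylim,
         bandwidth = density$bandwidth),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
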