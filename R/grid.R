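#' Spatial grid geometry
#'
#' A regular lon/lat (WGS84) lattice shared by every raster layer in an
#' analysis. Cells are half-open `[edge, edge + cell_size)` in both axes,
#' row 1 is the northernmost row (north-up convention) and indices are
#' 1-based, following R matrix conventions.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param x_min,y_min Coordinates of the south-west corner, decimal degrees.
#' @param cell_size Cell edge length in degrees.
#' @return An object of class `sdm_grid`.
#' @examples
#' g <- sdm_grid(6, 8, x_min = 100, y_min = 20, cell_size = 0.5)
#' g$x_max; g$y_max
#' @export
sdm_grid <- function(n_rows, n_cols, x_min, y_min, cell_size) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  g <- structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    x_min = x_min, y_min = y_min,
    x_max = x_min + n_cols * cell_size,
    y_max = y_min + n_rows * cell_size,
    cell_size = cell_size
  ), class = "sdm_grid")
  g
}

#' @export
print.sdm_grid <- function(x, ...) {
  cat(sprintf("<sdm_grid> %d rows x %d cols, cell %g deg\n  extent: lon [%g, %g), lat [%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_min - b$x_min) < tol && abs(a$y_min - b$y_min) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Map points to grid cells
#'
#' Converts lon/lat points to (row, col) indices under the half-open cell
#' convention. Points outside the extent get NA.
#'
#' @param grid An [sdm_grid()].
#' @param lon,lat Numeric vectors of coordinates.
#' @return A data.frame with columns `row`, `col` (1-based; NA outside extent).
#' @export
cell_of <- function(grid, lon, lat) {
  col <- floor((lon - grid$x_min) / grid$cell_size) + 1L
  # cells are half-open [edge, edge + cell_size) in both axes; row 1 = north
  row <- grid$n_rows - floor((lat - grid$y_min) / grid$cell_size)
  bad <- lon < grid$x_min | lon >= grid$x_max | lat < grid$y_min | lat >= grid$y_max
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#'
#' @param grid An [sdm_grid()].
#' @param row,col Cell indices (vectors, 1-based).
#' @return data.frame with `lon`, `lat` of cell centers.
#' @export
cell_center <- function(grid, row, col) {
  data.frame(
    lon = grid$x_min + (col - 0.5) * grid$cell_size,
    lat = grid$y_max - (row - 0.5) * grid$cell_size
  )
}

#' Spherical cell areas
#'
#' Area of a grid cell on the authalic sphere (radius 6371.0088 km):
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`. The area depends on
#' the row (latitude band) only.
#'
#' @param grid An [sdm_grid()].
#' @param row Row index vector; defaults to all rows.
#' @return Numeric vector of areas in km^2, one per requested row.
#' @examples
#' g <- sdm_grid(2, 2, -1, -1, 1)   # 1-degree cells straddling the equator
#' cell_area(g, 1)
#' @export
cell_area <- function(grid, row = seq_len(grid$n_rows)) {
  stopifnot(all(row >= 1L), all(row <= grid$n_rows))
  R <- 6371.0088
  lat_top <- grid$y_max - (row - 1) * grid$cell_size
  lat_bot <- lat_top - grid$cell_size
  R^2 * (grid$cell_size * pi / 180) * (sinpi(lat_top / 180) - sinpi(lat_bot / 180))
}

#' Total area of a set of cells
#'
#' @param grid An [sdm_grid()].
#' @param mask Logical or 0/1 matrix (`n_rows x n_cols`); NA counts as 0.
#' @return Total area in km^2 of the TRUE/1 cells.
#' @export
mask_area <- function(grid, mask) {
  stopifnot(nrow(mask) == grid$n_rows, ncol(mask) == grid$n_cols)
  per_row <- cell_area(grid)
  m <- !is.na(mask) & mask != 0
  sum(per_row * rowSums(m))
}

#' Raster layer on a grid
#'
#' @param grid An [sdm_grid()].
#' @param values Numeric matrix `n_rows x n_cols`; NA marks missing data.
#' @param name Layer name.
#' @param kind `"continuous"` or `"categorical"`. Categorical layers must
#'   hold integer codes (or NA).
#' @return An object of class `sdm_raster`.
#' @export
sdm_raster <- function(grid, values, name, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("values must be a ", grid$n_rows, " x ", grid$n_cols, " matrix")
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical layer '", name, "' contains non-integer codes")
  }
  structure(list(grid = grid, name = name, kind = kind, values = values),
            class = "sdm_raster")
}

#' @export
print.sdm_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<sdm_raster> '%s' (%s), %d x %d, %d missing, range [%g, %g]\n",
              x$name, x$kind, x$grid$n_rows, x$grid$n_cols,
              sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Predictor stack
#'
#' An ordered collection of co-registered raster layers for one climate
#' scenario. All layers must share one grid and have unique names.
#'
#' @param layers List of [sdm_raster()] objects.
#' @param scenario_id Scenario label, e.g. `"current"` or `"rcp85-2050"`.
#' @return An object of class `sdm_stack`.
#' @export
sdm_stack <- function(layers, scenario_id = "current") {
  stopifnot(length(layers) >= 1)
  nm <- vapply(layers, function(l) l$name, "")
  if (anyDuplicated(nm)) stop("duplicate layer names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  g <- layers[[1]]$grid
  for (l in layers[-1]) if (!grids_equal(g, l$grid))
    stop("layer '", l$name, "' is on a different grid than '", layers[[1]]$name, "'")
  names(layers) <- nm
  structure(list(layers = layers, scenario_id = scenario_id, grid = g),
            class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("<sdm_stack> scenario '%s': %d layers [%s] on %d x %d grid\n",
              x$scenario_id, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

layer_names <- function(stack) names(stack$layers)

#' Extract feature rows from a stack
#'
#' Builds the per-cell feature table used for model fitting and projection.
#' Categorical layers come back as factors.
#'
#' @param stack An [sdm_stack()].
#' @param cells data.frame with `row`, `col` (defaults to every cell in
#'   row-major order).
#' @param variables Layer names to extract (defaults to all).
#' @return data.frame of feature values, one row per cell; NA where the
#'   layer is missing.
#' @export
extract_features <- function(stack, cells = NULL, variables = layer_names(stack)) {
  g <- stack$grid
  if (is.null(cells)) {
    cells <- expand.grid(col = seq_len(g$n_cols), row = seq_len(g$n_rows))[, c("row", "col")]
  }
  missing_vars <- setdiff(variables, layer_names(stack))
  if (length(missing_vars))
    stop("stack '", stack$scenario_id, "' lacks variables: ",
         paste(missing_vars, collapse = ", "))
  idx <- cbind(cells$row, cells$col)
  out <- lapply(variables, function(v) {
    l <- stack$layers[[v]]
    vals <- l$values[idx]
    if (l$kind == "categorical") factor(vals) else vals
  })
  names(out) <- variables
  as.data.frame(out, optional = TRUE)
}
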