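#' Read presence records from delimited text
#'
#' Expects a header with at least `species`, `lon`, `lat` (an optional
#' `source` column is kept as per-point provenance). Rows outside the grid
#' extent are counted and reported via the `n_rejected` attribute rather
#' than silently dropped; rows with non-numeric coordinates are an error
#' identifying the offending line.
#'
#' @param path CSV file path.
#' @param grid An [sdm_grid()] defining the study extent.
#' @return An object of class `sdm_occurrences`: list with `species`,
#'   `points` (data.frame lon/lat/source), and attributes `n_rejected`,
#'   `rejected` (the out-of-extent rows).
#' @export
read_occurrences <- function(path, grid) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("species", "lon", "lat")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("occurrence file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- which(is.na(lon) | is.na(lat))
  if (length(bad))
    stop("non-numeric coordinates in ", path, " at line ", bad[1] + 1L,
         " (value '", raw$lon[bad[1]], "', '", raw$lat[bad[1]], "')")
  src <- if ("source" %in% names(raw)) raw$source else rep("", nrow(raw))
  pts <- data.frame(lon = lon, lat = lat, source = src,
                    stringsAsFactors = FALSE)
  inside <- !is.na(cell_of(grid, lon, lat)$row)
  occurrences(species = if (nrow(raw)) raw$species[1] else "",
              points = pts[inside, , drop = FALSE],
              rejected = pts[!inside, , drop = FALSE])
}

#' Construct an occurrence set
#'
#' @param species Species name.
#' @param points data.frame with `lon`, `lat` (and optionally `source`).
#' @param rejected Optional data.frame of rows refused at load time.
#' @return An `sdm_occurrences` object.
#' @export
occurrences <- function(species, points, rejected = points[0, , drop = FALSE]) {
  if (is.null(points$source)) points$source <- rep("", nrow(points))
  rownames(points) <- NULL
  structure(list(species = species, points = points),
            n_rejected = nrow(rejected), rejected = rejected,
            class = "sdm_occurrences")
}

#' @export
print.sdm_occurrences <- function(x, ...) {
  cat(sprintf("<sdm_occurrences> '%s': %d points (%d rejected at load)\n",
              x$species, nrow(x$points), attr(x, "n_rejected")))
  invisible(x)
}

#' Write presence records
#'
#' @param occ An `sdm_occurrences` object.
#' @param path Output CSV path.
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(species = occ$species,
                   lon = occ$points$lon, lat = occ$points$lat,
                   source = occ$points$source)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-band georeferenced raster (ESRI ASCII grid)
#'
#' Plain-text north-up raster with square cells: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, northernmost row first.
#' Nodata cells become NA.
#'
#' @param path File path (conventionally `.asc`).
#' @param name Layer name; defaults to the file name without extension.
#' @param kind `"continuous"` or `"categorical"`.
#' @return An [sdm_raster()].
#' @export
read_raster <- function(path, name = NULL,
                        kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("raster ", path, " lacks header field(s): ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (any(c("dx", "dy", "xdim", "ydim") %in% names(hdr)))
    stop("unsupported geometry in ", path, ": non-square or rotated cells")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("raster ", path, ": expected ", hdr$nrows * hdr$ncols,
         " values, found ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  g <- sdm_grid(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
  sdm_raster(g, m, name = name, kind = kind)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param layer An [sdm_raster()].
#' @param path Output path.
#' @param nodata Sentinel written for NA cells.
#' @param digits Significant digits for values.
#' @export
write_raster <- function(layer, path, nodata = -9999, digits = 10) {
  g <- layer$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$x_min),
           sprintf("yllcorner %.10g", g$y_min),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  m <- layer$values
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a predictor stack from a directory of ASCII rasters
#'
#' @param paths Character vector of raster paths (layer order preserved).
#' @param scenario_id Scenario label for the stack.
#' @param categorical Layer names to load as categorical.
#' @return An [sdm_stack()].
#' @export
read_stack <- function(paths, scenario_id = "current", categorical = character()) {
  layers <- lapply(paths, function(p) {
    nm <- sub("\\.[^.]*$", "", basename(p))
    read_raster(p, kind = if (nm %in% categorical) "categorical" else "continuous")
  })
  sdm_stack(layers, scenario_id = scenario_id)
}

#' Write every layer of a stack
#'
#' @param stack An [sdm_stack()].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(stack$layers, function(l) {
    p <- file.path(dir, paste0(l$name, ".asc"))
    write_raster(l, p)
    p
  }, "")
  invisible(paths)
}

#' Construct a protected-area set
#'
#' @param areas List of areas; each a list with `id`, `name`, `ring`
#'   (data.frame lon/lat closed or open polygon ring), `protected_species`
#'   (character vector), `protected_ecosystem` (single label or "").
#' @return An object of class `sdm_pa_set`.
#' @export
protected_areas <- function(areas) {
  ids <- vapply(areas, function(a) as.character(a$id), "")
  if (anyDuplicated(ids)) stop("duplicate protected-area ids")
  for (a in areas) {
    r <- a$ring
    if (!is.data.frame(r) || nrow(r) < 3)
      stop("protected area ", a$id, ": ring must have >= 3 vertices")
  }
  structure(list(areas = areas), class = "sdm_pa_set")
}

#' @export
print.sdm_pa_set <- function(x, ...) {
  cat(sprintf("<sdm_pa_set> %d protected areas\n", length(x$areas)))
  invisible(x)
}

#' Read protected areas from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with properties `id`,
#' `name`, `protected_species` (semicolon-separated) and
#' `protected_ecosystem`. Only the outer ring of each polygon is used.
#'
#' @param path GeoJSON file path.
#' @return An `sdm_pa_set`.
#' @export
read_protected_areas <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$features)) stop(path, " is not a GeoJSON FeatureCollection")
  areas <- lapply(j$features, function(f) {
    if (f$geometry$type != "Polygon")
      stop("unsupported geometry type '", f$geometry$type, "' in ", path)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(p)
      data.frame(lon = p[[1]], lat = p[[2]])))
    p <- f$properties
    sp <- if (is.null(p$protected_species) || p$protected_species == "")
      character() else strsplit(p$protected_species, ";")[[1]]
    list(id = as.character(p$id), name = p$name %||% "", ring = ring,
         protected_species = trimws(sp),
         protected_ecosystem = p$protected_ecosystem %||% "")
  })
  protected_areas(areas)
}

#' Write protected areas as GeoJSON
#'
#' @param pas An `sdm_pa_set`.
#' @param path Output path.
#' @export
write_protected_areas <- function(pas, path) {
  feats <- lapply(pas$areas, function(a) {
    ring <- a$ring
    if (ring$lon[1] != ring$lon[nrow(ring)] || ring$lat[1] != ring$lat[nrow(ring)])
      ring <- rbind(ring, ring[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(i) c(ring$lon[i], ring$lat[i]))
    list(type = "Feature",
         properties = list(id = a$id, name = a$name,
                           protected_species = paste(a$protected_species, collapse = ";"),
                           protected_ecosystem = a$protected_ecosystem),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
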