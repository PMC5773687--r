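#' Round half away from zero
#'
#' Reporting convention for net range-change percentages: `+15` style
#' signed integers, halves rounded away from zero (so 0.5 -> 1, -0.5 -> -1),
#' unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Net range-change percent
#'
#' `round(100 * (gain - loss) / current)` with half-away-from-zero
#' rounding — the arithmetic behind "+15 %"-style range-shift summaries.
#'
#' @param current_km2,loss_km2,gain_km2 Areas in km^2.
#' @return Signed integer percent.
#' @export
net_change_pct <- function(current_km2, loss_km2, gain_km2) {
  round_half_away(100 * (gain_km2 - loss_km2) / current_km2)
}

#' Range change between two binary maps (full dispersal)
#'
#' Classifies every non-missing cell: loss (suitable now, not in the
#' future), stable (suitable in both periods), gain (suitable only in the
#' future), and sums spherical cell areas per class. Under full dispersal
#' the species may occupy any newly suitable cell, so
#' `future = stable + gain` exactly and `current = stable + loss` exactly.
#'
#' @param current,future `sdm_range_map` objects (or 0/1 [sdm_raster()]s)
#'   on the same grid.
#' @param cell_areas Optional per-row area vector overriding the
#'   spherical areas (e.g. `rep(1, n_rows)` for unit-cell tests).
#' @return An `sdm_range_change`: species, scenario_id, `current_km2`,
#'   `loss_km2`, `stable_km2`, `gain_km2`, `future_km2`, `net_pct`, and
#'   the three class masks.
#' @export
summarize_range_change <- function(current, future, cell_areas = NULL) {
  cur_l <- if (inherits(current, "sdm_range_map")) current$layer else current
  fut_l <- if (inherits(future, "sdm_range_map")) future$layer else future
  if (!grids_equal(cur_l$grid, fut_l$grid))
    stop("range change: current and future maps are on different grids")
  g <- cur_l$grid
  if (is.null(cell_areas)) cell_areas <- cell_area(g)
  stopifnot(length(cell_areas) == g$n_rows)
  cur <- cur_l$values; fut <- fut_l$values
  ok <- !is.na(cur) & !is.na(fut)
  loss   <- ok & cur == 1 & fut == 0
  stable <- ok & cur == 1 & fut == 1
  gain   <- ok & cur == 0 & fut == 1
  area_of <- function(m) sum(cell_areas * rowSums(m))
  loss_km2 <- area_of(loss); stable_km2 <- area_of(stable); gain_km2 <- area_of(gain)
  current_km2 <- loss_km2 + stable_km2
  structure(list(
    species = if (inherits(current, "sdm_range_map")) current$species else NA_character_,
    scenario_id = if (inherits(future, "sdm_range_map")) future$scenario_id else NA_character_,
    current_km2 = current_km2, loss_km2 = loss_km2, stable_km2 = stable_km2,
    gain_km2 = gain_km2, future_km2 = stable_km2 + gain_km2,
    net_pct = net_change_pct(current_km2, loss_km2, gain_km2),
    masks = list(loss = sdm_raster(g, loss + 0, "loss"),
                 stable = sdm_raster(g, stable + 0, "stable"),
                 gain = sdm_raster(g, gain + 0, "gain"))),
    class = "sdm_range_change")
}

#' @export
print.sdm_range_change <- function(x, ...) {
  cat(sprintf(
    "<sdm_range_change> %s -> %s\n  current %.0f km2 | loss %.0f | stable %.0f | gain %.0f | net %+d%%\n",
    x$species, x$scenario_id, x$current_km2, x$loss_km2, x$stable_km2,
    x$gain_km2, x$net_pct))
  invisible(x)
}

# even-odd ray casting, vertices-as-rings; points exactly on an edge are
# resolved by the half-open crossing rule (consistent, not symmetric)
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  xs <- ring$lon; ys <- ring$lat
  if (xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n]; n <- n - 1L }
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > lat) != (ys[j] > lat)) &
      (lon < (xs[j] - xs[i]) * (lat - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Rasterize a protected-area polygon
#'
#' Cell-center containment: a cell belongs to the reserve iff its center
#' lies inside the polygon's outer ring (even-odd rule).
#'
#' @param area One element of an `sdm_pa_set$areas` list (needs `ring`).
#' @param grid An [sdm_grid()].
#' @return 0/1 matrix mask (`n_rows x n_cols`); a warning is issued if the
#'   polygon covers no cell center.
#' @export
rasterize_protected_area <- function(area, grid) {
  rc <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  ctr <- cell_center(grid, rc$row, rc$col)
  inside <- point_in_ring(ctr$lon, ctr$lat, area$ring)
  m <- matrix(0, grid$n_rows, grid$n_cols)
  m[cbind(rc$row, rc$col)] <- inside + 0
  if (!any(inside))
    warning("protected area ", area$id, " covers no cell center on this grid")
  m
}

#' Flag protected areas newly exposed to invasion
#'
#' A reserve is potentially threatened under a future scenario iff the
#' species' current range does not overlap it at all but its future range
#' does. Overlap means at least one suitable cell whose center falls
#' inside the reserve polygon; `overlap_km2` is the area of
#' future-suitable cells inside the reserve.
#'
#' @param current,future `sdm_range_map` objects on one grid.
#' @param pas An `sdm_pa_set`.
#' @return data.frame, one row per reserve: `area_id`, `name`, `species`,
#'   `scenario`, `threatened`, `overlap_km2`, `current_overlap_km2`,
#'   `affected_species` (semicolon-joined), `affected_ecosystem`.
#' @export
assess_pa_threat <- function(current, future, pas) {
  g <- current$layer$grid
  if (!grids_equal(g, future$layer$grid))
    stop("threat assessment: maps on different grids")
  cur <- current$layer$values; fut <- future$layer$values
  rows <- lapply(pas$areas, function(a) {
    m <- rasterize_protected_area(a, g)
    cur_ov <- mask_area(g, m == 1 & !is.na(cur) & cur == 1)
    fut_ov <- mask_area(g, m == 1 & !is.na(fut) & fut == 1)
    data.frame(area_id = a$id, name = a$name, species = current$species,
               scenario = future$scenario_id,
               threatened = cur_ov == 0 && fut_ov > 0,
               overlap_km2 = fut_ov, current_overlap_km2 = cur_ov,
               affected_species = paste(a$protected_species, collapse = ";"),
               affected_ecosystem = a$protected_ecosystem,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate threats and range changes into a risk report
#'
#' Per (species, scenario): the number of threatened reserves, the number
#' of distinct protected plant species and ecosystems inside them
#' (deduplicated across reserves), and the total threatened reserve area;
#' plus the range-change account table.
#'
#' @param threats data.frame rows from [assess_pa_threat()] (possibly
#'   several species/scenarios bound together).
#' @param changes List of `sdm_range_change` objects.
#' @return An `sdm_risk_report`: list with `risk` (summary data.frame),
#'   `range_change` (data.frame), `pa_threats` (threatened rows only).
#' @export
build_risk_report <- function(threats, changes) {
  combos <- unique(threats[c("species", "scenario")])
  risk <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- threats[threats$species == combos$species[i] &
                     threats$scenario == combos$scenario[i] &
                     threats$threatened, , drop = FALSE]
    sp <- unlist(strsplit(sub$affected_species[sub$affected_species != ""], ";"))
    eco <- sub$affected_ecosystem[sub$affected_ecosystem != ""]
    data.frame(species = combos$species[i], scenario = combos$scenario[i],
               n_reserves = nrow(sub),
               n_affected_plant_species = length(unique(trimws(sp))),
               n_affected_ecosystems = length(unique(eco)),
               total_area_km2 = sum(sub$overlap_km2),
               stringsAsFactors = FALSE)
  }))
  rc <- do.call(rbind, lapply(changes, function(ch)
    data.frame(species = ch$species, scenario = ch$scenario_id,
               current_km2 = ch$current_km2, loss_km2 = ch$loss_km2,
               stable_km2 = ch$stable_km2, gain_km2 = ch$gain_km2,
               net_pct = ch$net_pct, stringsAsFactors = FALSE)))
  structure(list(risk = risk, range_change = rc,
                 pa_threats = threats[threats$threatened, , drop = FALSE]),
            class = "sdm_risk_report")
}

#' @export
print.sdm_risk_report <- function(x, ...) {
  cat("<sdm_risk_report>\nRange change:\n")
  print(x$range_change, row.names = FALSE)
  cat("Invasion risk to protected areas:\n")
  print(x$risk, row.names = FALSE)
  invisible(x)
}

#' Write the risk report tables
#'
#' Emits `rangechange.csv`, `risk.csv` and `pa_threats.csv`.
#'
#' @param report An `sdm_risk_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_risk_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$range_change, file.path(dir, "rangechange.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$risk, file.path(dir, "risk.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$pa_threats, file.path(dir, "pa_threats.csv"),
                   row.names = FALSE)
  invisible(dir)
}
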