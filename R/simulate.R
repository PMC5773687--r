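#' Virtual landscape and virtual species simulation
#'
#' These generators supply every input the range-shift pipeline consumes —
#' climate predictor stacks for a baseline and warmed scenarios,
#' presence-only occurrence records drawn from a known Gaussian niche, and
#' rectangular protected areas with species/ecosystem attributes — together
#' with the ground-truth range masks needed for recovery tests. A virtual
#' species with an analytically known niche is the standard way to validate
#' a distribution-modelling pipeline: the estimate can be scored against
#' truth, which real presence-only data never allows.
#'
#' @name simulate
NULL

# Deterministic seed derivation: one global seed fans out to independent
# per-stage streams. Simple 32-bit mixing keeps results < 2^31.
derive_seed <- function(base, ...) {
  ks <- c(base, ...)
  h <- 0
  for (k in ks) {
    kk <- sum(utf8ToInt(paste0(k))) + 1
    h <- (h * 69069 + kk * 2654435761) %% 2147483647
  }
  as.integer(h %% 2147483562) + 1L
}

#' Landscape scenario configuration
#'
#' Each layer is a tilted plane plus smoothed Gaussian noise:
#' `value = intercept + slope * (cos(a) * lon + sin(a) * lat) + noise`,
#' with `a = direction` in degrees (0 = increasing eastward, 90 =
#' increasing northward), `slope` in layer units per degree, and noise
#' drawn iid N(0, noise_sd) then box-smoothed over a square window of
#' radius `smooth` cells. Future scenarios add a constant `delta` per
#' layer while reusing the baseline noise field, so the stated deltas are
#' the only difference between periods.
#'
#' @param grid An [sdm_grid()].
#' @param layers Named list of recipes, each
#'   `list(direction =, slope =, intercept =, noise_sd =, smooth =)`.
#' @param future_deltas Named list: scenario label -> named numeric vector
#'   of additive shifts (layers not named shift by 0).
#' @param seed Integer seed for the noise fields.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(grid, layers, future_deltas = list(), seed = 1L) {
  for (nm in names(layers)) {
    r <- layers[[nm]]
    if (!all(c("direction", "slope", "intercept", "noise_sd", "smooth") %in% names(r)))
      stop("layer recipe '", nm, "' is incomplete")
    if (r$smooth <= 0) stop("layer recipe '", nm, "': smoothing radius must be positive")
    if (r$noise_sd < 0) stop("layer recipe '", nm, "': noise sd must be >= 0")
  }
  for (sc in names(future_deltas)) {
    d <- future_deltas[[sc]]
    if (!length(d) || all(d == 0))
      stop("future scenario '", sc, "' must shift at least one layer")
    if (!all(names(d) %in% names(layers)))
      stop("future scenario '", sc, "' shifts unknown layer(s)")
  }
  structure(list(grid = grid, layers = layers, future_deltas = future_deltas,
                 seed = as.integer(seed)), class = "scenario_config")
}

# box smoothing with edge renormalization (mean over in-grid window)
smooth_field <- function(m, radius) {
  r <- as.integer(radius)
  if (r == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  # separable box filter via cumulative sums
  box1d <- function(x, r) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    hi <- pmin(seq_len(n) + r, n); lo <- pmax(seq_len(n) - r, 1L)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m2 <- apply(m, 2, box1d, r = r)
  t(apply(m2, 1, box1d, r = r))
}

#' Simulate baseline and future predictor stacks
#'
#' @param cfg A [scenario_config()].
#' @return Named list of [sdm_stack()]: `current` plus one per future
#'   scenario label. Bit-identical across runs with the same seed.
#' @export
simulate_landscape <- function(cfg) {
  g <- cfg$grid
  lon_c <- g$x_min + (seq_len(g$n_cols) - 0.5) * g$cell_size
  lat_c <- g$y_max - (seq_len(g$n_rows) - 0.5) * g$cell_size
  lon <- matrix(lon_c, g$n_rows, g$n_cols, byrow = TRUE)
  lat <- matrix(lat_c, g$n_rows, g$n_cols)
  current <- list()
  for (nm in names(cfg$layers)) {
    r <- cfg$layers[[nm]]
    a <- r$direction * pi / 180
    plane <- r$intercept + r$slope * (cos(a) * lon + sin(a) * lat)
    noise <- 0
    if (r$noise_sd > 0) {
      set.seed(derive_seed(cfg$seed, "landscape", nm))
      raw <- matrix(stats::rnorm(g$n_rows * g$n_cols, sd = r$noise_sd),
                    g$n_rows, g$n_cols)
      noise <- smooth_field(raw, r$smooth)
    }
    current[[nm]] <- sdm_raster(g, plane + noise, name = nm)
  }
  out <- list(current = sdm_stack(current, scenario_id = "current"))
  for (sc in names(cfg$future_deltas)) {
    d <- cfg$future_deltas[[sc]]
    shifted <- lapply(current, function(l) {
      dl <- if (l$name %in% names(d)) d[[l$name]] else 0
      sdm_raster(g, l$values + dl, name = l$name)
    })
    out[[sc]] <- sdm_stack(shifted, scenario_id = sc)
  }
  out
}

#' Virtual species configuration
#'
#' The niche is a product of independent Gaussian responses: suitability at
#' a cell with predictor values x is `prod_v exp(-(x_v - mu_v)^2 / (2 sigma_v^2))`,
#' reaching 1 where every variable sits at its optimum. The true range is
#' the set of cells with suitability at or above `suitability_threshold`.
#'
#' @param niche Named list: variable -> `c(mu, sigma)`, sigma > 0.
#' @param suitability_threshold Probability in (0, 1) defining the true range.
#' @param n_presences Number of presence points to draw.
#' @param sampling_seed Integer seed for presence sampling.
#' @param detection_bias Multiplier on acceptance probability (capped at 1).
#' @return A `species_config` list.
#' @export
species_config <- function(niche, suitability_threshold = 0.2,
                           n_presences = 300, sampling_seed = 1L,
                           detection_bias = 1) {
  for (v in names(niche)) {
    if (length(niche[[v]]) != 2 || niche[[v]][2] <= 0)
      stop("niche for '", v, "' must be c(mu, sigma) with sigma > 0")
  }
  stopifnot(suitability_threshold > 0, suitability_threshold < 1,
            n_presences >= 1, detection_bias > 0)
  structure(list(niche = niche, suitability_threshold = suitability_threshold,
                 n_presences = as.integer(n_presences),
                 sampling_seed = as.integer(sampling_seed),
                 detection_bias = detection_bias), class = "species_config")
}

#' True habitat suitability of a virtual species
#'
#' @param stack An [sdm_stack()] holding every niche variable.
#' @param cfg A [species_config()].
#' @return An [sdm_raster()] with values in \[0, 1\] (NA where any niche
#'   variable is missing).
#' @export
true_suitability <- function(stack, cfg) {
  miss <- setdiff(names(cfg$niche), layer_names(stack))
  if (length(miss))
    stop("stack lacks niche variable(s): ", paste(miss, collapse = ", "))
  g <- stack$grid
  s <- matrix(1, g$n_rows, g$n_cols)
  for (v in names(cfg$niche)) {
    mu <- cfg$niche[[v]][1]; sg <- cfg$niche[[v]][2]
    s <- s * exp(-(stack$layers[[v]]$values - mu)^2 / (2 * sg^2))
  }
  sdm_raster(g, s, name = "suitability")
}

#' True range mask of a virtual species
#'
#' @param stack An [sdm_stack()].
#' @param cfg A [species_config()].
#' @return An [sdm_raster()] with 0/1 values (1 where suitability >= the
#'   configured threshold).
#' @export
true_range <- function(stack, cfg) {
  s <- true_suitability(stack, cfg)
  sdm_raster(s$grid, (s$values >= cfg$suitability_threshold) + 0,
             name = "true_range")
}

#' Sample presence-only occurrence records
#'
#' Emulates opportunistic herbarium-style records: candidate cells are
#' drawn uniformly among non-missing cells and accepted with probability
#' `suitability * detection_bias` (capped at 1) until `n_presences` points
#' are accepted; each accepted draw places one point uniformly inside its
#' cell. Cells may be drawn repeatedly.
#'
#' @param suitability An [sdm_raster()] with values in \[0, 1\].
#' @param cfg A [species_config()].
#' @param species Species name for the output set.
#' @return An `sdm_occurrences` object.
#' @export
sample_presences <- function(suitability, cfg, species = "virtual_species") {
  g <- suitability$grid
  p <- pmin(as.vector(t(suitability$values)) * cfg$detection_bias, 1)  # row-major
  valid <- which(!is.na(p))
  if (!length(valid) || all(p[valid] == 0))
    stop("cannot sample presences: suitability is identically 0")
  set.seed(cfg$sampling_seed)
  need <- cfg$n_presences
  rows <- integer(0); cols <- integer(0)
  while (need > 0) {
    k <- max(64L, ceiling(need / max(mean(p[valid]), 1e-6)))
    cand <- sample(valid, k, replace = TRUE)
    keep <- cand[stats::runif(k) < p[cand]]
    keep <- keep[seq_len(min(length(keep), need))]
    if (length(keep)) {
      rows <- c(rows, (keep - 1L) %/% g$n_cols + 1L)
      cols <- c(cols, (keep - 1L) %% g$n_cols + 1L)
      need <- need - length(keep)
    }
  }
  ctr <- cell_center(g, rows, cols)
  lon <- ctr$lon + (stats::runif(length(rows)) - 0.5) * g$cell_size
  lat <- ctr$lat + (stats::runif(length(rows)) - 0.5) * g$cell_size
  occurrences(species, data.frame(lon = lon, lat = lat,
                                  source = "simulated"))
}

.pa_species_pool <- c(
  "Taxus chinensis", "Ginkgo biloba", "Bretschneidera sinensis",
  "Alsophila spinulosa", "Davidia involucrata", "Cathaya argyrophylla",
  "Metasequoia glyptostroboides", "Abies beshanzuensis",
  "Cycas panzhihuaensis", "Emmenopterys henryi")

.pa_ecosystem_pool <- c(
  "subtropical evergreen broadleaf forest", "mid-subtropical forest",
  "tropical monsoon rainforest", "montane conifer forest",
  "karst seasonal rainforest", "river-valley savanna")

#' Simulate rectangular protected areas
#'
#' Places `n` non-overlapping axis-aligned rectangles inside the grid
#' extent, each assigned 0-3 protected plant species and one ecosystem
#' label from fixed vocabularies.
#'
#' @param grid An [sdm_grid()].
#' @param n Number of reserves.
#' @param seed Integer seed.
#' @param size_range Rectangle edge lengths, in degrees (min, max).
#' @param max_tries Placement attempts before giving up.
#' @return An `sdm_pa_set`.
#' @export
simulate_protected_areas <- function(grid, n, seed = 1L,
                                     size_range = c(0.5, 1.5) * grid$cell_size * 4,
                                     max_tries = 200L * n) {
  stopifnot(n >= 1)
  set.seed(seed)
  placed <- list()
  tries <- 0L
  while (length(placed) < n && tries < max_tries) {
    tries <- tries + 1L
    w <- stats::runif(1, size_range[1], size_range[2])
    h <- stats::runif(1, size_range[1], size_range[2])
    x0 <- stats::runif(1, grid$x_min, grid$x_max - w)
    y0 <- stats::runif(1, grid$y_min, grid$y_max - h)
    clash <- any(vapply(placed, function(r)
      x0 < r$x1 && x0 + w > r$x0 && y0 < r$y1 && y0 + h > r$y0, TRUE))
    if (!clash) placed[[length(placed) + 1L]] <-
        list(x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h)
  }
  if (length(placed) < n)
    stop("could not place ", n, " disjoint reserves in ", max_tries, " attempts")
  areas <- lapply(seq_len(n), function(i) {
    r <- placed[[i]]
    n_sp <- sample(0:3, 1)
    list(id = sprintf("PA%03d", i),
         name = sprintf("Simulated Reserve %d", i),
         ring = data.frame(lon = c(r$x0, r$x1, r$x1, r$x0),
                           lat = c(r$y0, r$y0, r$y1, r$y1)),
         protected_species = if (n_sp) sample(.pa_species_pool, n_sp) else character(),
         protected_ecosystem = sample(.pa_ecosystem_pool, 1))
  })
  protected_areas(areas)
}

#' Ground truth for a simulated study
#'
#' Computes the true current and future range masks of the virtual species
#' and the true net range change per future scenario, using the same area
#' accounting as the pipeline's range-change summary.
#'
#' @param stacks Named list of stacks from [simulate_landscape()].
#' @param cfg A [species_config()].
#' @return List with `true_current_range`, `true_future_range` (named list
#'   of masks), and `true_net_change_pct` (named numeric, signed percent).
#' @export
ground_truth <- function(stacks, cfg) {
  cur <- true_range(stacks$current, cfg)
  fut <- lapply(stacks[setdiff(names(stacks), "current")], true_range, cfg = cfg)
  g <- cur$grid
  net <- vapply(fut, function(f) {
    cur_km2 <- mask_area(g, cur$values)
    loss <- mask_area(g, cur$values == 1 & f$values == 0)
    gain <- mask_area(g, cur$values == 0 & f$values == 1)
    round_half_away(100 * (gain - loss) / cur_km2)
  }, 0)
  list(true_current_range = cur, true_future_range = fut,
       true_net_change_pct = net)
}

#' Default demonstration study
#'
#' The bundled virtual study emulating a subtropical invasive woody plant:
#' a 60 x 80 grid over 95-115 E, 20-35 N at 0.25 degrees; an annual-mean
#' temperature layer falling 0.7 degrees C per degree of latitude, an
#' annual-precipitation layer rising west to east, and a collinear
#' temperature-seasonality layer included to exercise predictor pruning.
#' Two warming scenarios add +1 and +2 degrees C to temperature. The
#' species' thermal optimum sits at the warm (southern) edge so warming
#' expands its true range northward.
#'
#' @param seed Integer seed driving landscape noise and presence sampling.
#' @param n_presences Number of presence records to draw.
#' @return List with `stacks`, `species_cfg`, `occurrences`, `truth`,
#'   `protected_areas`, and the `scenario_cfg` used.
#' @export
demo_study <- function(seed = 1L, n_presences = 300L) {
  g <- sdm_grid(60, 80, x_min = 95, y_min = 20, cell_size = 0.25)
  sc <- scenario_config(
    g,
    layers = list(
      tmean = list(direction = 90, slope = -0.7, intercept = 28 + 0.7 * 20,
                   noise_sd = 0.5, smooth = 2),
      prec  = list(direction = 0, slope = 40, intercept = 600 - 40 * 95,
                   noise_sd = 30, smooth = 2),
      tseas = list(direction = 90, slope = 2.1, intercept = 40 - 2.1 * 20,
                   noise_sd = 1.0, smooth = 2)
    ),
    future_deltas = list(`warm-low-2050` = c(tmean = 1.0),
                         `warm-high-2050` = c(tmean = 2.0)),
    seed = derive_seed(seed, "landscape")
  )
  stacks <- simulate_landscape(sc)
  sp <- species_config(
    niche = list(tmean = c(30, 2.5), prec = c(1000, 300)),
    suitability_threshold = 0.2, n_presences = n_presences,
    sampling_seed = derive_seed(seed, "presences")
  )
  # records are drawn from occupied sites only: detection follows suitability
  # but a herbarium record can only come from inside the species' true range
  suit <- true_suitability(stacks$current, sp)
  rng <- true_range(stacks$current, sp)
  occ_suit <- sdm_raster(g, suit$values * rng$values, name = "occupied_suitability")
  occ <- sample_presences(occ_suit, sp, species = "virtual_invader")
  pas <- simulate_protected_areas(g, n = 25, seed = derive_seed(seed, "reserves"))
  list(stacks = stacks, species_cfg = sp, occurrences = occ,
       truth = ground_truth(stacks, sp), protected_areas = pas,
       scenario_cfg = sc)
}
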