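#' Spatial filtering of occurrence records
#'
#' Reduces sampling bias by merging all records falling in the same grid
#' cell into one occurrence; the representative point of a cell is the
#' first record encountered in input order. With the default ~10 km cells
#' this reproduces the standard coarse-grid thinning used before fitting
#' distribution models to herbarium data.
#'
#' @param occ An `sdm_occurrences` object.
#' @param grid An [sdm_grid()]; typically the analysis grid itself.
#' @return An object of class `sdm_filtered`: list with `species`, `cells`
#'   (data.frame row/col, one per occupied cell), `representative_points`
#'   (data.frame lon/lat aligned with `cells`), and `grid`.
#' @export
spatial_filter <- function(occ, grid) {
  pts <- occ$points
  cc <- cell_of(grid, pts$lon, pts$lat)
  if (any(is.na(cc$row)))
    stop("spatial_filter: ", sum(is.na(cc$row)), " point(s) outside the grid extent")
  key <- (cc$row - 1L) * grid$n_cols + cc$col
  first <- !duplicated(key)
  structure(list(species = occ$species,
                 cells = data.frame(row = cc$row[first], col = cc$col[first]),
                 representative_points = data.frame(lon = pts$lon[first],
                                                    lat = pts$lat[first]),
                 grid = grid),
            class = "sdm_filtered")
}

#' @export
print.sdm_filtered <- function(x, ...) {
  cat(sprintf("<sdm_filtered> '%s': %d occupied cells\n",
              x$species, nrow(x$cells)))
  invisible(x)
}

#' Greedy collinearity pruning by Pearson correlation
#'
#' Scans continuous predictors in a user-supplied priority order (most
#' ecologically relevant first) and keeps a variable iff its absolute
#' Pearson correlation with every already-kept variable does not exceed
#' the threshold. Categorical layers pass through untested. Correlations
#' are computed over a seeded random sample of cells that are non-missing
#' in all continuous layers.
#'
#' @param stack An [sdm_stack()].
#' @param threshold Correlation magnitude above which a variable is
#'   dropped (default 0.8).
#' @param priority Ordered character vector covering every continuous
#'   layer; earlier names win ties.
#' @param max_cells Cap on the number of cells used (default 10000).
#' @param seed Seed for the cell sample.
#' @return An object of class `sdm_prune`: `kept` (ordered names,
#'   categorical layers appended), `dropped` (data.frame dropped /
#'   retained_partner / r), `threshold`.
#' @export
pearson_prune <- function(stack, threshold = 0.8,
                          priority = layer_names(stack),
                          max_cells = 10000L, seed = 1L) {
  stopifnot(threshold > 0, threshold <= 1)
  kinds <- vapply(stack$layers, function(l) l$kind, "")
  cont <- names(stack$layers)[kinds == "continuous"]
  cat_vars <- names(stack$layers)[kinds == "categorical"]
  priority <- intersect(priority, cont)
  if (!setequal(priority, cont))
    stop("priority must cover all continuous layers; missing: ",
         paste(setdiff(cont, priority), collapse = ", "))
  feat <- extract_features(stack, variables = cont)
  ok <- stats::complete.cases(feat)
  idx <- which(ok)
  if (length(idx) < 3)
    stop("insufficient data: only ", length(idx),
         " complete cells available for correlation")
  if (length(idx) > max_cells) {
    set.seed(seed)
    idx <- sort(sample(idx, max_cells))
  }
  feat <- feat[idx, , drop = FALSE]
  kept <- character()
  dropped <- data.frame(dropped = character(), retained_partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  for (v in priority) {
    partner <- NA_character_; rmax <- 0
    for (k in kept) {
      if (stats::sd(feat[[v]]) == 0 || stats::sd(feat[[k]]) == 0) next
      r <- stats::cor(feat[[v]], feat[[k]])
      if (abs(r) > abs(rmax)) { rmax <- r; partner <- k }
    }
    if (!is.na(partner) && abs(rmax) > threshold) {
      dropped <- rbind(dropped, data.frame(dropped = v, retained_partner = partner,
                                           r = rmax, stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, v)
    }
  }
  structure(list(kept = c(kept, cat_vars), dropped = dropped,
                 threshold = threshold), class = "sdm_prune")
}

#' @export
print.sdm_prune <- function(x, ...) {
  cat(sprintf("<sdm_prune> kept %d variable(s): %s\n", length(x$kept),
              paste(x$kept, collapse = ", ")))
  if (nrow(x$dropped))
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped %s (r = %.3f with %s)\n", x$dropped$dropped[i],
                  x$dropped$r[i], x$dropped$retained_partner[i]))
  invisible(x)
}

#' Sample pseudo-absence cells outside a suitability envelope
#'
#' Draws background cells uniformly without replacement from the cells the
#' envelope scores 0 (and that are non-missing and not presence cells).
#' This is the envelope-exclusion scheme: candidate absences are
#' restricted to areas the presence envelope deems unsuitable.
#'
#' @param envelope An [sdm_raster()] with 0/1 values (NA = missing).
#' @param n Number of cells to draw.
#' @param seed Integer seed.
#' @param exclude data.frame with `row`, `col` of cells never to sample
#'   (typically presence cells).
#' @return data.frame with `row`, `col` of the sampled cells.
#' @export
sample_pseudo_absences <- function(envelope, n, seed,
                                   exclude = data.frame(row = integer(), col = integer())) {
  stopifnot(n >= 1)
  g <- envelope$grid
  eligible <- which(!is.na(envelope$values) & envelope$values == 0)  # column-major
  if (nrow(exclude)) {
    excl <- (exclude$col - 1L) * g$n_rows + exclude$row
    eligible <- setdiff(eligible, excl)
  }
  if (length(eligible) < n)
    stop("insufficient background: need ", n, " cells outside the envelope, only ",
         length(eligible), " eligible (short by ", n - length(eligible), ")")
  set.seed(seed)
  pick <- if (length(eligible) == 1) eligible else sample(eligible, n)
  data.frame(row = (pick - 1L) %% g$n_rows + 1L,
             col = (pick - 1L) %/% g$n_rows + 1L)
}

#' Build presence / pseudo-absence training sets
#'
#' For each pseudo-absence replicate: presence feature rows are extracted
#' at the filtered representative points, an envelope (fit on those same
#' presences) defines the exclusion zone, and `n_pa` background cells are
#' drawn outside it with a replicate-specific seed. Presence rows with a
#' missing feature are dropped with a message.
#'
#' @param filtered An `sdm_filtered` object.
#' @param stack The baseline [sdm_stack()].
#' @param kept Character vector of predictor names to use (e.g. the
#'   `kept` field of [pearson_prune()]).
#' @param n_pa Pseudo-absences per replicate; default equals the presence
#'   count (a balanced design).
#' @param n_replicates Number of pseudo-absence replicates (default 3).
#' @param base_seed Seed from which replicate seeds are derived.
#' @param sre_q Envelope tail fraction used for the exclusion zone.
#' @return List of `sdm_training` objects, one per replicate: each has
#'   `species`, `replicate_id`, `data` (features + `label` 1/0 +
#'   `row`/`col`), `schema`, `pa_seed`.
#' @export
build_training_sets <- function(filtered, stack, kept, n_pa = NULL,
                                n_replicates = 3L, base_seed = 1L,
                                sre_q = 0.025) {
  pres_feat <- extract_features(stack, cells = filtered$cells, variables = kept)
  ok <- stats::complete.cases(pres_feat)
  if (any(!ok))
    message("build_training_sets: dropping ", sum(!ok),
            " presence cell(s) with missing predictor values")
  pres_feat <- pres_feat[ok, , drop = FALSE]
  pres_cells <- filtered$cells[ok, , drop = FALSE]
  if (nrow(pres_feat) < 2) stop("fewer than 2 usable presence rows")
  if (is.null(n_pa)) n_pa <- nrow(pres_feat)
  kinds <- vapply(stack$layers[kept], function(l) l$kind, "")
  schema <- data.frame(variable = kept, kind = kinds, stringsAsFactors = FALSE,
                       row.names = NULL)
  env <- sre_fit(pres_feat, q = sre_q, schema = schema)
  env_map <- predict_layer(env, stack, name = "sre_envelope")
  lapply(seq_len(n_replicates), function(r) {
    seed_r <- derive_seed(base_seed, "pseudo_absence", r)
    pa_cells <- sample_pseudo_absences(env_map, n = n_pa, seed = seed_r,
                                       exclude = pres_cells)
    pa_feat <- extract_features(stack, cells = pa_cells, variables = kept)
    dat <- rbind(
      cbind(pres_feat, label = 1L, pres_cells),
      cbind(pa_feat, label = 0L, pa_cells)
    )
    rownames(dat) <- NULL
    structure(list(species = filtered$species, replicate_id = r,
                   data = dat, schema = schema, pa_seed = seed_r),
              class = "sdm_training")
  })
}

#' @export
print.sdm_training <- function(x, ...) {
  cat(sprintf("<sdm_training> '%s' replicate %d: %d presences, %d pseudo-absences, %d predictors\n",
              x$species, x$replicate_id, sum(x$data$label == 1),
              sum(x$data$label == 0), nrow(x$schema)))
  invisible(x)
}
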