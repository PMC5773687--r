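#' Build a TSS-weighted ensemble model
#'
#' For every (algorithm, pseudo-absence replicate) combination whose mean
#' TSS across split replicates exceeds the retention threshold, the
#' learner is refit on that replicate's full training set and enters the
#' ensemble with weight equal to its mean TSS. Combinations at or below
#' the threshold are excluded — in practice the plain range envelope is
#' usually the member dropped this way. Weights are normalized to sum 1
#' at prediction time.
#'
#' @param records Evaluation records from [evaluate_design()].
#' @param training_sets List of `sdm_training` (indexed by `replicate_id`).
#' @param retention_tss_min Minimum mean TSS to retain a member
#'   (default 0.7).
#' @param seed Base seed for the refits.
#' @return An object of class `sdm_ensemble` with `members` (each
#'   `list(model, weight, algorithm, pa_rep)`), `retention_tss_min`,
#'   `binarization_threshold` (NA until set), `species`.
#' @export
build_ensemble <- function(records, training_sets, retention_tss_min = 0.7,
                           seed = 1L) {
  agg <- stats::aggregate(tss ~ algorithm + pa_rep, data = records, FUN = mean)
  keep <- agg[agg$tss > retention_tss_min, , drop = FALSE]
  if (!nrow(keep))
    stop("empty ensemble: no algorithm x replicate combination has mean TSS > ",
         retention_tss_min, " (best: ", format(max(agg$tss), digits = 3),
         "); consider relaxing retention_tss_min")
  by_rep <- stats::setNames(training_sets,
                            vapply(training_sets, function(t) t$replicate_id, 1L))
  members <- lapply(seq_len(nrow(keep)), function(i) {
    ts <- by_rep[[as.character(keep$pa_rep[i])]]
    model <- fit_learner(keep$algorithm[i], ts,
                         seed = derive_seed(seed, "refit", keep$algorithm[i],
                                            keep$pa_rep[i]))
    list(model = model, weight = keep$tss[i],
         algorithm = keep$algorithm[i], pa_rep = keep$pa_rep[i])
  })
  structure(list(members = members, retention_tss_min = retention_tss_min,
                 binarization_threshold = NA_real_,
                 species = training_sets[[1]]$species,
                 schema = training_sets[[1]]$schema),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> '%s': %d member(s), retention TSS > %g, threshold %s\n",
              x$species, length(x$members), x$retention_tss_min,
              if (is.na(x$binarization_threshold)) "unset"
              else format(x$binarization_threshold, digits = 4)))
  for (m in x$members)
    cat(sprintf("  %s (PA rep %d), weight %.3f\n", m$algorithm, m$pa_rep, m$weight))
  invisible(x)
}

#' Ensemble scores for feature rows
#'
#' Weighted average of member predictions, weights normalized to sum 1.
#'
#' @param ens An `sdm_ensemble`.
#' @param newdata data.frame holding the schema variables.
#' @return Numeric scores in \[0, 1\]; NA where predictors are missing.
#' @export
predict_ensemble <- function(ens, newdata) {
  w <- vapply(ens$members, function(m) m$weight, 0)
  w <- w / sum(w)
  preds <- vapply(ens$members,
                  function(m) predict_learner(m$model, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  as.numeric(preds %*% w)
}

#' Project an ensemble onto a scenario stack
#'
#' @param ens An `sdm_ensemble`.
#' @param stack An [sdm_stack()] holding every schema variable.
#' @return An `sdm_suitability`: list with `layer` ([sdm_raster()] of
#'   scores), `species`, `scenario_id`.
#' @export
project_ensemble <- function(ens, stack) {
  miss <- setdiff(ens$schema$variable, layer_names(stack))
  if (length(miss))
    stop("projection error: stack '", stack$scenario_id,
         "' lacks variable(s): ", paste(miss, collapse = ", "))
  feat <- extract_features(stack, variables = ens$schema$variable)
  scores <- predict_ensemble(ens, feat)
  g <- stack$grid
  layer <- sdm_raster(g, matrix(scores, g$n_rows, g$n_cols, byrow = TRUE),
                      name = paste0(ens$species, "_", stack$scenario_id, "_suit"))
  structure(list(layer = layer, species = ens$species,
                 scenario_id = stack$scenario_id),
            class = "sdm_suitability")
}

#' Fix the ensemble's binarization threshold
#'
#' Chooses the max-TSS cut-off of the ensemble's scores against the full
#' presence / pseudo-absence data (all replicates pooled). The threshold
#' is set once from the baseline scenario and reused for every future
#' projection, so that range gain/loss comparisons use one rule.
#'
#' @param ens An `sdm_ensemble`.
#' @param training_sets The list of `sdm_training` the ensemble was built
#'   from (pooled for the threshold).
#' @return The ensemble with `binarization_threshold` set.
#' @export
set_binarization_threshold <- function(ens, training_sets) {
  pooled <- do.call(rbind, lapply(training_sets, function(t) t$data))
  scores <- predict_ensemble(ens, pooled[ens$schema$variable])
  keep <- !is.na(scores)
  mt <- max_tss_threshold(scores[keep], pooled$label[keep])
  ens$binarization_threshold <- mt$threshold
  ens
}

#' Binarize a suitability map
#'
#' @param sm An `sdm_suitability` (or bare [sdm_raster()]).
#' @param threshold Score cut-off in \[0, 1\]; `score >= threshold` is
#'   suitable. Missing cells stay missing.
#' @return An `sdm_range_map`: list with `layer` (0/1 raster),
#'   `threshold`, `species`, `scenario_id`.
#' @export
binarize <- function(sm, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  layer <- if (inherits(sm, "sdm_suitability")) sm$layer else sm
  vals <- (layer$values >= threshold) + 0
  structure(list(
    layer = sdm_raster(layer$grid, vals,
                       name = sub("_suit$", "_bin", layer$name)),
    threshold = threshold,
    species = if (inherits(sm, "sdm_suitability")) sm$species else NA_character_,
    scenario_id = if (inherits(sm, "sdm_suitability")) sm$scenario_id else NA_character_),
    class = "sdm_range_map")
}
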