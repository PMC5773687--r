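#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults. A single
#' global `seed` fans out into independent, replayable per-stage streams
#' (landscape noise, presence sampling, pseudo-absence replicates, splits,
#' learner fits) via a deterministic mixing scheme, so replicates are
#' independent yet any run is reproducible from its manifest.
#'
#' @param ... Overrides for any default (nested lists merged one level
#'   deep).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    filter = list(cell_size_deg = NULL),  # NULL = use the stack's own grid
    prune = list(threshold = 0.8, priority = NULL, max_cells = 10000L),
    pa = list(n = NULL, replicates = 3L, sre_q = 0.025),
    learners = list(enabled = c("GLM", "SRE")),
    evaluation = list(n_splits = 5L, fraction = 0.7, mode = "repeated"),
    ensemble = list(retention_tss_min = 0.7),
    output_dir = NULL
  )
  over <- list(...)
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(cfg[[k]])) {
      for (kk in names(over[[k]])) cfg[[k]][[kk]] <- over[[k]][[kk]]
    } else cfg[[k]] <- over[[k]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full range-shift risk pipeline
#'
#' End-to-end: spatial filtering -> collinearity pruning -> envelope-based
#' pseudo-absence replicates -> (algorithms x splits) evaluation ->
#' TSS-weighted ensemble -> projection per scenario -> max-TSS
#' binarization (threshold fixed on the baseline) -> range-change
#' accounting -> protected-area overlay -> risk report. With the classic
#' design (3 pseudo-absence replicates, 9 algorithms, 5 splits) this
#' produces 135 evaluation records per species per time period.
#'
#' @param occ An `sdm_occurrences` object.
#' @param stacks Named list of [sdm_stack()]s: `current` plus future
#'   scenarios.
#' @param pas An `sdm_pa_set` (optional; NULL skips the overlay).
#' @param cfg A [run_config()].
#' @return An `sdm_run`: list with `filtered`, `prune`, `training_sets`,
#'   `records`, `evaluation_summary`, `ensemble`, `suitability` (per
#'   scenario), `range_maps` (per scenario), `changes`, `threats`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(occ, stacks, pas = NULL, cfg = run_config()) {
  if (is.null(stacks$current)) stop("stage input: stacks must include 'current'")
  current <- stacks$current
  futures <- stacks[setdiff(names(stacks), "current")]

  filtered <- spatial_filter(occ, current$grid)

  priority <- cfg$prune$priority %||% layer_names(current)
  prune <- pearson_prune(current, threshold = cfg$prune$threshold,
                         priority = priority,
                         max_cells = cfg$prune$max_cells,
                         seed = derive_seed(cfg$seed, "prune"))

  training_sets <- build_training_sets(
    filtered, current, kept = prune$kept, n_pa = cfg$pa$n,
    n_replicates = cfg$pa$replicates, base_seed = cfg$seed,
    sre_q = cfg$pa$sre_q)

  records <- evaluate_design(training_sets,
                             algorithms = cfg$learners$enabled,
                             n_splits = cfg$evaluation$n_splits,
                             fraction = cfg$evaluation$fraction,
                             seed = cfg$seed,
                             split_mode = cfg$evaluation$mode)

  ens <- build_ensemble(records, training_sets,
                        retention_tss_min = cfg$ensemble$retention_tss_min,
                        seed = cfg$seed)
  ens <- set_binarization_threshold(ens, training_sets)

  suitability <- lapply(stacks, function(s) project_ensemble(ens, s))
  range_maps <- lapply(suitability, binarize, threshold = ens$binarization_threshold)

  changes <- lapply(names(futures), function(sc)
    summarize_range_change(range_maps$current, range_maps[[sc]]))
  names(changes) <- names(futures)

  threats <- NULL
  report <- NULL
  if (!is.null(pas)) {
    threats <- do.call(rbind, lapply(names(futures), function(sc)
      assess_pa_threat(range_maps$current, range_maps[[sc]], pas)))
    report <- build_risk_report(threats, changes)
  }

  manifest <- list(
    species = occ$species,
    seed = cfg$seed,
    config = unclass(cfg),
    n_occurrences = nrow(occ$points),
    n_filtered = nrow(filtered$cells),
    kept_variables = prune$kept,
    n_evaluation_records = nrow(records),
    ensemble_members = lapply(ens$members, function(m)
      list(algorithm = m$algorithm, pa_rep = m$pa_rep, weight = m$weight)),
    binarization_threshold = ens$binarization_threshold,
    scenarios = names(stacks),
    r_version = as.character(getRversion())
  )

  run <- structure(list(filtered = filtered, prune = prune,
                        training_sets = training_sets, records = records,
                        evaluation_summary = summarize_evaluation(records),
                        ensemble = ens, suitability = suitability,
                        range_maps = range_maps, changes = changes,
                        threats = threats, report = report,
                        manifest = manifest),
                   class = "sdm_run")

  if (!is.null(cfg$output_dir)) write_run(run, cfg$output_dir)
  run
}

#' @export
print.sdm_run <- function(x, ...) {
  cat(sprintf("<sdm_run> '%s': %d filtered cells, %d evaluation records, %d ensemble member(s)\n",
              x$manifest$species, x$manifest$n_filtered,
              x$manifest$n_evaluation_records, length(x$ensemble$members)))
  for (sc in names(x$changes)) {
    ch <- x$changes[[sc]]
    cat(sprintf("  %s: net %+d%% (loss %.0f, stable %.0f, gain %.0f km2)\n",
                sc, ch$net_pct, ch$loss_km2, ch$stable_km2, ch$gain_km2))
  }
  if (!is.null(x$report)) {
    for (i in seq_len(nrow(x$report$risk)))
      cat(sprintf("  %s: %d reserve(s) newly exposed, %.0f km2\n",
                  x$report$risk$scenario[i], x$report$risk$n_reserves[i],
                  x$report$risk$total_area_km2[i]))
  }
  invisible(x)
}

#' Write run outputs to disk
#'
#' Evaluation records and summary as CSV, suitability and binary maps as
#' ASCII rasters, report tables as CSV, and a YAML manifest sufficient to
#' replay the run.
#'
#' @param run An `sdm_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$records, file.path(dir, "evaluation.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$evaluation_summary, file.path(dir, "evaluation_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  for (sc in names(run$suitability)) {
    write_raster(run$suitability[[sc]]$layer,
                 file.path(dir, paste0(run$manifest$species, "_", sc, "_suit.asc")))
    write_raster(run$range_maps[[sc]]$layer,
                 file.path(dir, paste0(run$manifest$species, "_", sc, "_bin.asc")))
  }
  if (!is.null(run$report)) write_risk_report(run$report, dir)
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
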