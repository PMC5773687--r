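#' Stratified train/test split plans
#'
#' Draws `n_splits` independent stratified random splits (default 70/30):
#' within each label class, a `fraction` share of rows (rounded) goes to
#' the training side. A true partitioning k-fold mode is available via
#' `mode = "kfold"`, in which case `n_splits` folds are formed per class
#' and plan i holds out fold i.
#'
#' @param training An `sdm_training` object (or any list with a `data`
#'   data.frame containing `label`).
#' @param n_splits Number of split replicates (default 5).
#' @param fraction Training fraction for `mode = "repeated"` (default 0.7).
#' @param seed Integer seed.
#' @param mode `"repeated"` (independent splits) or `"kfold"`.
#' @return List of plans: each `list(replicate_id, train, test)` with row
#'   indices into `training$data`.
#' @export
make_splits <- function(training, n_splits = 5L, fraction = 0.7, seed = 1L,
                        mode = c("repeated", "kfold")) {
  mode <- match.arg(mode)
  stopifnot(n_splits >= 1, fraction > 0, fraction < 1)
  lab <- training$data$label
  idx1 <- which(lab == 1); idx0 <- which(lab == 0)
  if (!length(idx1) || !length(idx0)) stop("both classes must be present")
  set.seed(seed)
  if (mode == "repeated") {
    n1 <- round(fraction * length(idx1)); n0 <- round(fraction * length(idx0))
    if (n1 %in% c(0, length(idx1)) || n0 %in% c(0, length(idx0)))
      stop("split would leave a class absent from train or test")
    lapply(seq_len(n_splits), function(s) {
      tr <- c(sample(idx1, n1), sample(idx0, n0))
      list(replicate_id = s, train = sort(tr), test = sort(setdiff(c(idx1, idx0), tr)))
    })
  } else {
    f1 <- sample(rep_len(seq_len(n_splits), length(idx1)))
    f0 <- sample(rep_len(seq_len(n_splits), length(idx0)))
    if (length(idx1) < n_splits || length(idx0) < n_splits)
      stop("k-fold split would leave a class absent from a test fold")
    lapply(seq_len(n_splits), function(s) {
      te <- c(idx1[f1 == s], idx0[f0 == s])
      list(replicate_id = s, train = sort(setdiff(c(idx1, idx0), te)),
           test = sort(te))
    })
  }
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly drawn
#' presence outscores a randomly drawn absence, ties counted one half.
#'
#' @param scores Numeric suitability scores.
#' @param labels 0/1 labels of the same length.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic from a confusion table
#'
#' `TSS = sensitivity + specificity - 1`, with sensitivity `tp/(tp+fn)`
#' and specificity `tn/(tn+fp)`. Prevalence-invariant, range \[-1, 1\].
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return TSS value.
#' @export
tss <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn == 0 || tn + fp == 0)
    stop("TSS undefined: a class has zero count")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

confusion <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  c(tp = sum(pred & labels == 1), fn = sum(!pred & labels == 1),
    tn = sum(!pred & labels == 0), fp = sum(pred & labels == 0))
}

#' Threshold maximizing the true skill statistic
#'
#' Probes every distinct score value as a candidate cut-off under the rule
#' `score >= threshold -> presence` and returns the smallest candidate
#' attaining the maximal TSS (a deterministic tie-break).
#'
#' @param scores Numeric suitability scores.
#' @param labels 0/1 labels.
#' @return List with `threshold` and `tss` at that threshold.
#' @export
max_tss_threshold <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("max-TSS threshold undefined: both classes must be present")
  cand <- sort(unique(scores))
  # sweep candidates from high to low, maintaining cumulative counts
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]; l_sorted <- labels[ord]
  cum1 <- cumsum(l_sorted == 1); cum0 <- cumsum(l_sorted == 0)
  # for threshold t: predicted positive = scores >= t
  pos_at <- findInterval(-cand, -s_sorted)  # count of scores >= cand
  tp <- cum1[pos_at]; fp <- cum0[pos_at]
  tss_at <- tp / n1 + (n0 - fp) / n0 - 1
  best <- max(tss_at)
  t_best <- min(cand[tss_at >= best - 1e-12])
  list(threshold = t_best, tss = tss_at[match(t_best, cand)])
}

#' Evaluate one model run
#'
#' Fits the given algorithm on the plan's training rows and scores it on
#' the held-out rows only: AUC plus TSS at the max-TSS threshold.
#'
#' @param algorithm_id Registered learner name.
#' @param training An `sdm_training` object.
#' @param split One plan from [make_splits()].
#' @param seed Seed handed to the learner fit.
#' @return One-row data.frame: `species`, `algorithm`, `pa_rep`,
#'   `split_rep`, `auc`, `tss`, `threshold`.
#' @export
evaluate_run <- function(algorithm_id, training, split, seed = 1L) {
  dat <- training$data
  tr <- structure(list(species = training$species,
                       replicate_id = training$replicate_id,
                       data = dat[split$train, , drop = FALSE],
                       schema = training$schema, pa_seed = training$pa_seed),
                  class = "sdm_training")
  model <- fit_learner(algorithm_id, tr, seed = seed)
  test <- dat[split$test, , drop = FALSE]
  scores <- predict_learner(model, test[training$schema$variable])
  keep <- !is.na(scores)
  mt <- max_tss_threshold(scores[keep], test$label[keep])
  data.frame(species = training$species, algorithm = algorithm_id,
             pa_rep = training$replicate_id, split_rep = split$replicate_id,
             auc = auc(scores[keep], test$label[keep]),
             tss = mt$tss, threshold = mt$threshold,
             stringsAsFactors = FALSE)
}

#' Run the full evaluation design
#'
#' Crosses pseudo-absence replicates x algorithms x split replicates —
#' the classic 3 x 9 x 5 = 135-run ensemble design when nine algorithms
#' are registered — and returns one evaluation record per run.
#'
#' @param training_sets List of `sdm_training` (one per pseudo-absence
#'   replicate).
#' @param algorithms Character vector of registered learner names.
#' @param n_splits Split replicates per training set (default 5).
#' @param fraction Training fraction (default 0.7).
#' @param seed Base seed; per-replicate seeds are derived from it.
#' @param split_mode Passed to [make_splits()].
#' @return data.frame of evaluation records (one row per run).
#' @export
evaluate_design <- function(training_sets, algorithms = c("GLM", "SRE"),
                            n_splits = 5L, fraction = 0.7, seed = 1L,
                            split_mode = "repeated") {
  recs <- list()
  for (ts in training_sets) {
    splits <- make_splits(ts, n_splits = n_splits, fraction = fraction,
                          seed = derive_seed(seed, "split", ts$replicate_id),
                          mode = split_mode)
    for (alg in algorithms) {
      for (sp in splits) {
        recs[[length(recs) + 1L]] <-
          evaluate_run(alg, ts, sp,
                       seed = derive_seed(seed, "fit", alg, ts$replicate_id,
                                          sp$replicate_id))
      }
    }
  }
  do.call(rbind, recs)
}

#' Summarize evaluation records per algorithm
#'
#' @param records data.frame from [evaluate_design()].
#' @return data.frame with mean AUC and mean TSS per algorithm.
#' @export
summarize_evaluation <- function(records) {
  agg <- stats::aggregate(cbind(auc, tss) ~ algorithm, data = records, FUN = mean)
  agg[order(-agg$tss), ]
}
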