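#' Surface range envelope (BIOCLIM-style) model
#'
#' The envelope keeps, per continuous predictor, the central
#' `1 - 2q` quantile interval of the presence values (linear-interpolation
#' quantiles). A site scores 1 iff every continuous predictor lies within
#' its interval, bounds inclusive; categorical predictors are ignored.
#'
#' @param presence_features data.frame of predictor values at presence
#'   sites.
#' @param q Tail fraction trimmed per side, in `[0, 0.5)`; default 0.025.
#' @param schema Optional data.frame `variable`/`kind`; defaults to
#'   treating every numeric column as continuous.
#' @return An object of class `sre_envelope` with `bounds` (named list of
#'   `c(low, high)`) and `q`.
#' @export
sre_fit <- function(presence_features, q = 0.025, schema = NULL) {
  stopifnot(q >= 0, q < 0.5, nrow(presence_features) >= 2)
  if (is.null(schema)) {
    kinds <- ifelse(vapply(presence_features, is.numeric, TRUE),
                    "continuous", "categorical")
    schema <- data.frame(variable = names(presence_features), kind = kinds,
                         stringsAsFactors = FALSE)
  }
  cont <- schema$variable[schema$kind == "continuous"]
  bounds <- lapply(cont, function(v) {
    x <- presence_features[[v]]
    x <- x[!is.na(x)]
    if (length(unique(x)) == 1 && q > 0)
      warning("SRE: variable '", v, "' constant across presences; bounds collapse")
    stats::quantile(x, probs = c(q, 1 - q), names = FALSE, type = 7)
  })
  names(bounds) <- cont
  structure(list(bounds = bounds, q = q, schema = schema),
            class = "sre_envelope")
}

#' @export
print.sre_envelope <- function(x, ...) {
  cat(sprintf("<sre_envelope> q = %g per side\n", x$q))
  for (v in names(x$bounds))
    cat(sprintf("  %s in [%g, %g]\n", v, x$bounds[[v]][1], x$bounds[[v]][2]))
  invisible(x)
}

#' Predict with a surface range envelope
#'
#' @param env An `sre_envelope`.
#' @param newdata data.frame holding every envelope variable.
#' @return 0/1 vector; NA where any envelope variable is missing.
#' @export
sre_predict <- function(env, newdata) {
  miss <- setdiff(names(env$bounds), names(newdata))
  if (length(miss)) stop("newdata lacks variable(s): ", paste(miss, collapse = ", "))
  inside <- rep(1, nrow(newdata))
  for (v in names(env$bounds)) {
    b <- env$bounds[[v]]
    x <- newdata[[v]]
    inside <- inside * ifelse(is.na(x), NA, as.numeric(x >= b[1] & x <= b[2]))
  }
  inside
}

#' Predict a fitted model over a whole stack
#'
#' @param model An `sre_envelope` or `sdm_fitted` learner.
#' @param stack An [sdm_stack()].
#' @param name Name for the output layer.
#' @return An [sdm_raster()] of scores; NA where any predictor is missing.
#' @export
predict_layer <- function(model, stack, name = "prediction") {
  vars <- if (inherits(model, "sre_envelope")) model$schema$variable
          else model$schema$variable
  feat <- extract_features(stack, variables = vars)
  scores <- if (inherits(model, "sre_envelope")) sre_predict(model, feat)
            else predict_learner(model, feat)
  g <- stack$grid
  # extract_features walks cells in row-major order
  m <- matrix(scores, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  sdm_raster(g, m, name = name)
}

# ---------------------------------------------------------------------------
# Learner contract: every algorithm is a pair
#   fit(training, seed)   -> sdm_fitted (with $algorithm_id, $schema)
#   predict(fitted, data) -> scores in [0, 1] (NA allowed for missing rows)

new_fitted <- function(algorithm_id, state, schema) {
  structure(list(algorithm_id = algorithm_id, state = state, schema = schema),
            class = "sdm_fitted")
}

#' Predict suitability scores with a fitted learner
#'
#' @param model An `sdm_fitted` object.
#' @param newdata data.frame of predictor values.
#' @return Numeric scores in \[0, 1\]; NA for rows with missing predictors.
#' @export
predict_learner <- function(model, newdata) {
  stopifnot(inherits(model, "sdm_fitted"))
  fn <- learner_spec(model$algorithm_id)$predict
  miss <- setdiff(model$schema$variable, names(newdata))
  if (length(miss)) stop("newdata lacks variable(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(newdata[model$schema$variable])
  out <- rep(NA_real_, nrow(newdata))
  if (any(cc)) out[cc] <- fn(model, newdata[cc, , drop = FALSE])
  out
}

#' Fit a registered learner on a training set
#'
#' @param algorithm_id Registered algorithm name (see [list_learners()]).
#' @param training An `sdm_training` object.
#' @param seed Seed handed to stochastic learners.
#' @param ... Extra arguments for the learner's fit function.
#' @return An `sdm_fitted` object.
#' @export
fit_learner <- function(algorithm_id, training, seed = 1L, ...) {
  fn <- learner_spec(algorithm_id)$fit
  m <- fn(training, seed = seed, ...)
  stopifnot(inherits(m, "sdm_fitted"))
  m
}

# --- native learner: logistic regression (GLM) ------------------------------

glm_formula <- function(schema, degree) {
  terms <- vapply(seq_len(nrow(schema)), function(i) {
    v <- schema$variable[i]
    if (schema$kind[i] == "categorical" || degree == 1) v
    else sprintf("%s + I(%s^2)", v, v)
  }, "")
  stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
}

glm_fit_native <- function(training, seed = 1L, degree = 2L) {
  stopifnot(degree %in% c(1L, 2L))
  dat <- training$data
  if (length(unique(dat$label)) < 2) stop("GLM needs both labels present")
  schema <- training$schema
  for (i in which(schema$kind == "categorical"))
    dat[[schema$variable[i]]] <- factor(dat[[schema$variable[i]]])
  form <- glm_formula(schema, degree)
  fit <- suppressWarnings(
    stats::glm(form, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  # (quasi-)separation: IRLS walks to the boundary — near-zero deviance,
  # non-convergence, or runaway coefficients
  separated <- !fit$converged || fit$deviance < 1e-6 ||
    max(abs(stats::coef(fit)), na.rm = TRUE) > 1e3
  state <- list(degree = degree)
  if (separated) {
    warning("GLM: quasi-separation detected; refitting with a small ridge penalty")
    mm <- stats::model.matrix(form, dat)
    state$ridge <- ridge_logistic(mm, dat$label, lambda = 1e-6)
    state$formula <- form
  } else {
    state$glm <- fit
  }
  new_fitted("GLM", state, schema)
}

glm_predict_native <- function(model, newdata) {
  schema <- model$schema
  st <- model$state
  for (i in which(schema$kind == "categorical"))
    newdata[[schema$variable[i]]] <- factor(newdata[[schema$variable[i]]])
  if (!is.null(st$glm)) {
    as.numeric(stats::predict(st$glm, newdata = newdata, type = "response"))
  } else {
    newdata$label <- 0L  # placeholder so the training formula expands
    mm <- stats::model.matrix(st$formula, newdata)
    as.numeric(stats::plogis(mm %*% st$ridge))
  }
}

# L2-penalized logistic regression by IRLS (intercept unpenalized); the
# stabilizing fallback when maximum likelihood walks to the boundary.
# Columns are standardized internally for conditioning; the returned
# coefficients are on the original feature scale.
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100L, tol = 1e-8) {
  p <- ncol(X)
  icpt <- which(colnames(X) == "(Intercept)")
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  ctr[icpt] <- 0; scl[icpt] <- 1
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pen <- diag(lambda, p)
  if (length(icpt)) pen[icpt, icpt] <- 0
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(Xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(Xs, w * Xs) + pen, crossprod(Xs, w * z)))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  out <- beta / scl
  if (length(icpt)) out[icpt] <- beta[icpt] - sum((beta * ctr / scl)[-icpt])
  out
}

# --- native learner: SRE wrapped in the contract ----------------------------

sre_fit_learner <- function(training, seed = 1L, q = 0.025) {
  pres <- training$data[training$data$label == 1, training$schema$variable,
                        drop = FALSE]
  env <- sre_fit(pres, q = q, schema = training$schema)
  new_fitted("SRE", list(envelope = env), training$schema)
}

sre_predict_learner <- function(model, newdata) {
  sre_predict(model$state$envelope, newdata)
}

# --- registry ---------------------------------------------------------------

.learners <- new.env(parent = emptyenv())

learner_spec <- function(algorithm_id) {
  if (!exists(algorithm_id, envir = .learners))
    stop("unknown learner '", algorithm_id, "'; registered: ",
         paste(list_learners(), collapse = ", "))
  get(algorithm_id, envir = .learners)
}

#' List registered learner algorithms
#' @return Character vector of algorithm ids.
#' @export
list_learners <- function() sort(ls(.learners))

#' Register a learner adapter
#'
#' Adapters plug additional algorithms (e.g. random forests, boosted
#' trees, neural networks) into the pipeline. At registration the adapter
#' is run through the learner contract on a small synthetic training set:
#' scores must lie in \[0, 1\], prediction must be deterministic given the
#' fitted state, and refitting with the same seed must reproduce the same
#' predictions. Violations refuse the registration.
#'
#' @param algorithm_id Name under which the algorithm is exposed.
#' @param fit_fn `function(training, seed, ...)` returning the opaque
#'   fitted state (any object).
#' @param predict_fn `function(state, newdata)` returning scores.
#' @param overwrite Allow replacing an existing registration.
#' @return `algorithm_id`, invisibly.
#' @export
register_adapter <- function(algorithm_id, fit_fn, predict_fn, overwrite = FALSE) {
  if (algorithm_id %in% list_learners() && !overwrite)
    stop("learner '", algorithm_id, "' already registered")
  spec <- list(
    fit = function(training, seed = 1L, ...) {
      new_fitted(algorithm_id, fit_fn(training, seed = seed, ...), training$schema)
    },
    predict = function(model, newdata) predict_fn(model$state, newdata)
  )
  check_learner_contract(spec, algorithm_id)
  assign(algorithm_id, spec, envir = .learners)
  invisible(algorithm_id)
}

#' Remove a registered adapter
#' @param algorithm_id Name to remove (native GLM/SRE cannot be removed).
#' @export
unregister_adapter <- function(algorithm_id) {
  if (algorithm_id %in% c("GLM", "SRE")) stop("cannot unregister a native learner")
  if (exists(algorithm_id, envir = .learners)) rm(list = algorithm_id, envir = .learners)
  invisible(NULL)
}

contract_training_set <- function(seed = 99L) {
  set.seed(seed)
  n <- 40L
  x1 <- c(stats::rnorm(n, 1), stats::rnorm(n, -1))
  x2 <- stats::rnorm(2 * n)
  structure(list(
    species = "contract_check", replicate_id = 1L,
    data = data.frame(x1 = x1, x2 = x2, label = rep(1:0, each = n),
                      row = 1L, col = seq_len(2 * n)),
    schema = data.frame(variable = c("x1", "x2"),
                        kind = "continuous", stringsAsFactors = FALSE),
    pa_seed = seed), class = "sdm_training")
}

#' Check a learner specification against the contract
#'
#' Public test helper: fits the candidate on a fixed synthetic training
#' set and verifies score range, determinism of prediction, and
#' reproducibility under a fixed seed.
#'
#' @param spec List with `fit(training, seed, ...)` and
#'   `predict(model, newdata)` in contract form.
#' @param algorithm_id Name used in error messages.
#' @return TRUE invisibly; stops with a contract violation otherwise.
#' @export
check_learner_contract <- function(spec, algorithm_id = "candidate") {
  ts <- contract_training_set()
  m1 <- spec$fit(ts, seed = 7L)
  probe <- ts$data[seq(1, nrow(ts$data), by = 3), c("x1", "x2")]
  s1 <- spec$predict(m1, probe)
  if (length(s1) != nrow(probe))
    stop("contract violation (", algorithm_id, "): prediction length mismatch")
  if (any(is.na(s1)))
    stop("contract violation (", algorithm_id, "): NA scores on complete rows")
  if (any(s1 < 0 | s1 > 1))
    stop("contract violation (", algorithm_id, "): scores outside [0, 1] (e.g. ",
         format(s1[which(s1 < 0 | s1 > 1)[1]]), ")")
  s1b <- spec$predict(m1, probe)
  if (!identical(s1, s1b))
    stop("contract violation (", algorithm_id, "): prediction not deterministic")
  m2 <- spec$fit(ts, seed = 7L)
  s2 <- spec$predict(m2, probe)
  if (max(abs(s1 - s2)) > 1e-12)
    stop("contract violation (", algorithm_id, "): refit with the same seed differs")
  invisible(TRUE)
}

# native learners are registered at load time
register_native_learners <- function() {
  assign("GLM", list(fit = glm_fit_native, predict = glm_predict_native),
         envir = .learners)
  assign("SRE", list(fit = sre_fit_learner, predict = sre_predict_learner),
         envir = .learners)
}

.onLoad <- function(libname, pkgname) register_native_learners()
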