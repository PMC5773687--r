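test_that("q = 0 gives a min-max envelope; values at a bound score 1", {
  pres <- data.frame(t = 10:20)
  env <- sre_fit(pres, q = 0)
  expect_equal(env$bounds$t, c(10, 20))
  expect_equal(sre_predict(env, data.frame(t = c(10, 20, 15, 9.999, 20.001))),
               c(1, 1, 1, 0, 0))
})

test_that("envelope quantiles match a brute-force sorted-percentile oracle", {
  set.seed(1)
  x <- rnorm(1000)
  env <- sre_fit(data.frame(t = x), q = 0.025)
  # oracle: linear-interpolation quantile computed by hand from the sort
  sorted <- sort(x)
  h <- function(p) {
    k <- (length(x) - 1) * p + 1
    lo <- floor(k); hi <- ceiling(k)
    sorted[lo] + (k - lo) * (sorted[hi] - sorted[lo])
  }
  expect_equal(env$bounds$t, c(h(0.025), h(0.975)), tolerance = 1e-12)
})

test_that("the envelope is a conjunction over variables", {
  pres <- data.frame(t = c(10, 20), p = c(100, 200))
  env <- sre_fit(pres, q = 0)
  grid <- expand.grid(t = c(5, 15, 25), p = c(50, 150, 250))
  got <- sre_predict(env, grid)
  want <- as.numeric(grid$t >= 10 & grid$t <= 20 & grid$p >= 100 & grid$p <= 200)
  expect_equal(got, want)
  # missing feature flags the row rather than guessing
  expect_true(is.na(sre_predict(env, data.frame(t = 15, p = NA))))
})

test_that("envelope predictions agree with per-row brute-force bound checks", {
  set.seed(3)
  pres <- data.frame(a = rnorm(200), b = runif(200), c = rnorm(200, 5, 2))
  env <- sre_fit(pres, q = 0.025)
  rows <- data.frame(a = rnorm(1000, sd = 2), b = runif(1000, -1, 2),
                     c = rnorm(1000, 5, 4))
  got <- sre_predict(env, rows)
  want <- vapply(seq_len(1000), function(i) {
    as.numeric(all(vapply(names(env$bounds), function(v)
      rows[[v]][i] >= env$bounds[[v]][1] && rows[[v]][i] <= env$bounds[[v]][2],
      TRUE)))
  }, 0)
  expect_equal(got, want)
})

test_that("the envelope widens monotonically as q decreases", {
  set.seed(2)
  pres <- data.frame(t = rnorm(500))
  qs <- c(0.2, 0.1, 0.05, 0.025, 0)
  widths <- vapply(qs, function(q) diff(sre_fit(pres, q = q)$bounds$t), 0)
  expect_true(all(diff(widths) >= 0))
})

test_that("a constant presence variable collapses the envelope with a warning", {
  pres <- data.frame(t = rep(7, 10), p = 1:10)
  expect_warning(env <- sre_fit(pres, q = 0.1), "constant across presences")
  expect_equal(env$bounds$t, c(7, 7))
})

test_that("logistic regression recovers known coefficients within 3 SE", {
  set.seed(5)
  n <- 2000
  x <- rnorm(n)
  eta <- -0.5 + 1.5 * x
  y <- rbinom(n, 1, plogis(eta))
  ts <- structure(list(
    species = "sim", replicate_id = 1L,
    data = data.frame(x = x, label = y, row = 1L, col = seq_len(n)),
    schema = data.frame(variable = "x", kind = "continuous",
                        stringsAsFactors = FALSE),
    pa_seed = 1L), class = "sdm_training")
  m <- fit_learner("GLM", ts, degree = 1)
  fit <- m$state$glm
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(est["(Intercept)"] - (-0.5)), 3 * se["(Intercept)"])
  expect_lt(abs(est["x"] - 1.5), 3 * se["x"])
})

test_that("labels independent of features give chance-level training AUC", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 400
    dat <- data.frame(x = rnorm(n), label = rbinom(n, 1, 0.5),
                      row = 1L, col = seq_len(n))
    ts <- structure(list(species = "null", replicate_id = 1L, data = dat,
                         schema = data.frame(variable = "x", kind = "continuous",
                                             stringsAsFactors = FALSE),
                         pa_seed = s), class = "sdm_training")
    m <- fit_learner("GLM", ts, degree = 1)
    auc(predict_learner(m, dat["x"]), dat$label)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("duplicating the whole training set leaves GLM coefficients unchanged", {
  ts <- toy_training(n_per_class = 60, shift = 1.5, seed = 8)
  ts2 <- ts
  ts2$data <- rbind(ts$data, ts$data)
  m1 <- fit_learner("GLM", ts)
  m2 <- fit_learner("GLM", ts2)
  expect_equal(coef(m1$state$glm), coef(m2$state$glm), tolerance = 1e-6)
})

test_that("GLM predictions are invariant to affine rescaling of a feature", {
  ts <- toy_training(n_per_class = 80, shift = 1.2, seed = 13)
  probe <- ts$data[c("temp", "moist")]
  m1 <- fit_learner("GLM", ts)
  p1 <- predict_learner(m1, probe)
  ts_r <- ts
  ts_r$data$temp <- 10 * ts$data$temp + 100
  m2 <- fit_learner("GLM", ts_r)
  probe_r <- probe; probe_r$temp <- 10 * probe$temp + 100
  p2 <- predict_learner(m2, probe_r)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("categorical predictors are one-hot encoded by the GLM", {
  set.seed(21)
  n <- 300
  soil <- sample(1:3, n, replace = TRUE)
  y <- rbinom(n, 1, c(0.2, 0.5, 0.8)[soil])
  ts <- structure(list(
    species = "cat", replicate_id = 1L,
    data = data.frame(soil = soil, label = y, row = 1L, col = seq_len(n)),
    schema = data.frame(variable = "soil", kind = "categorical",
                        stringsAsFactors = FALSE),
    pa_seed = 1L), class = "sdm_training")
  m <- fit_learner("GLM", ts)
  p <- predict_learner(m, data.frame(soil = 1:3))
  expect_equal(p, as.numeric(tapply(y, soil, mean)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("perfectly separated data falls back to a ridge fit", {
  set.seed(2)
  n <- 60
  x <- c(rnorm(n, 5), rnorm(n, -5))
  ts <- structure(list(
    species = "sep", replicate_id = 1L,
    data = data.frame(x = x, label = rep(1:0, each = n),
                      row = 1L, col = seq_len(2 * n)),
    schema = data.frame(variable = "x", kind = "continuous",
                        stringsAsFactors = FALSE),
    pa_seed = 1L), class = "sdm_training")
  expect_warning(m <- fit_learner("GLM", ts, degree = 1), "separation")
  p <- predict_learner(m, data.frame(x = c(5, -5)))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(p[1], 0.9); expect_lt(p[2], 0.1)
})

test_that("adapter registration enforces the learner contract", {
  on.exit(unregister_adapter("DUMMY05"), add = TRUE)
  register_adapter("DUMMY05",
                   fit_fn = function(training, seed, ...) list(),
                   predict_fn = function(state, newdata) rep(0.5, nrow(newdata)))
  expect_true("DUMMY05" %in% list_learners())
  ts <- toy_training()
  m <- fit_learner("DUMMY05", ts)
  expect_equal(predict_learner(m, ts$data[c("temp", "moist")]),
               rep(0.5, nrow(ts$data)))
  # out-of-range scores are refused at registration
  expect_error(register_adapter("BAD",
                                fit_fn = function(training, seed, ...) list(),
                                predict_fn = function(state, newdata)
                                  rep(1.2, nrow(newdata))),
               "outside \\[0, 1\\]")
  expect_false("BAD" %in% list_learners())
  # nondeterministic prediction is refused
  expect_error(register_adapter("NOISY",
                                fit_fn = function(training, seed, ...) list(),
                                predict_fn = function(state, newdata)
                                  runif(nrow(newdata))),
               "not deterministic")
  # seeded stochastic fits are accepted
  on.exit(unregister_adapter("SEEDED"), add = TRUE)
  register_adapter("SEEDED",
                   fit_fn = function(training, seed, ...) {
                     set.seed(seed); list(b = runif(1))
                   },
                   predict_fn = function(state, newdata)
                     rep(state$b, nrow(newdata)))
  expect_true("SEEDED" %in% list_learners())
})

test_that("native learners cannot be unregistered", {
  expect_error(unregister_adapter("GLM"), "native")
  expect_true(all(c("GLM", "SRE") %in% list_learners()))
})
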