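test_that("c-statistic matches the pair-counting oracle and its identities", {
  set.seed(111)
  p <- round(runif(50), 2)  # rounding forces ties
  y <- rbinom(50, 1, p)
  if (sum(y) == 0 || sum(y) == 50) y[1:2] <- c(0, 1)
  expect_equal(c_statistic(p, y), oracle_c_statistic(p, y))

  # invariance under strictly increasing transforms
  expect_equal(c_statistic(stats::qlogis(pmin(pmax(p, 0.01), 0.99)), y),
               c_statistic(pmin(pmax(p, 0.01), 0.99), y))
  expect_equal(c_statistic(p^3 + 2 * p, y), c_statistic(p, y))

  # perfect separation and no-signal limits
  expect_equal(c_statistic(c(rep(0.9, 5), rep(0.1, 5)),
                           c(rep(1, 5), rep(0, 5))), 1)
  set.seed(112)
  pn <- runif(20000)
  yn <- rbinom(20000, 1, 0.3)
  expect_equal(c_statistic(pn, yn), 0.5, tolerance = 0.02)

  expect_error(c_statistic(runif(10), rep(1, 10)), "both outcome classes")

  # cross-check against an established AUC implementation
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                            direction = "<")))
  expect_equal(c_statistic(p, y), auc_ref, tolerance = 1e-10)
})

test_that("logistic recalibration recovers intercept 0 / slope 1 under truth", {
  set.seed(113)
  p <- stats::plogis(rnorm(20000, -1, 1.2))
  y <- rbinom(length(p), 1, p)
  cal <- calibration_fit(p, y)
  expect_equal(cal$intercept, 0, tolerance = 0.05)
  expect_equal(cal$slope, 1, tolerance = 0.05)

  # doubling the linear predictor halves the slope exactly
  p2 <- stats::plogis(2 * stats::qlogis(p))
  cal2 <- calibration_fit(p2, y)
  expect_equal(cal2$slope, cal$slope / 2, tolerance = 1e-6)

  expect_error(calibration_fit(rep(0.3, 100), rbinom(100, 1, 0.3)),
               "degenerate")
})

test_that("apparent calibration slope of a fresh fit is 1 (ML identity)", {
  co <- make_test_cohort(3000, seed = 114)
  fit <- fit_model_pipeline(co, predictors = c("n_drugs", "bpmh_available"),
                            age_var = "age", age_powers = c(2, 3),
                            retention_alpha = 1)
  cal <- calibration_fit(predict_risk(fit, co), co$outcome)
  expect_equal(cal$slope, 1, tolerance = 1e-6)
  expect_equal(cal$intercept, 0, tolerance = 1e-6)
})

test_that("overfitted probabilities show slope < 1 on fresh data", {
  set.seed(115)
  n <- 120
  train <- data.frame(matrix(rnorm(n * 15), n))
  test <- data.frame(matrix(rnorm(4000 * 15), 4000))
  lp_true <- 0.5 * train$X1 - 1
  train$outcome <- rbinom(n, 1, stats::plogis(lp_true))
  test$outcome <- rbinom(4000, 1, stats::plogis(0.5 * test$X1 - 1))
  rich <- fit_logistic(as.matrix(train[, 1:15]), train$outcome,
                       retention_alpha = 1,
                       terms = lapply(paste0("X", 1:15), function(p)
                         list(name = p, source = p, transform = "identity",
                              power = NA_real_, scale = NA_real_)))
  p_test <- predict_risk(rich, test)
  expect_lt(calibration_fit(p_test, test$outcome)$slope, 1)
})

test_that("identity bootstrap replicates give zero optimism", {
  co <- make_test_cohort(600, seed = 116)
  model_fn <- function(dat) fit_model_pipeline(
    dat, predictors = c("n_drugs", "bpmh_available"), age_var = "age",
    age_powers = c(2, 3), retention_alpha = 1)
  rep1 <- bootstrap_validate(model_fn, co, b = 1, seed = 1,
                             index_fn = function(i, n) seq_len(n))
  expect_equal(rep1$corrected_c, rep1$apparent_c, tolerance = 1e-12)
  expect_equal(rep1$optimism_c, 0, tolerance = 1e-12)
  expect_equal(rep1$shrinkage_factor, rep1$apparent_slope, tolerance = 1e-9)
})

test_that("bootstrap validation is deterministic and detects overfitting", {
  set.seed(117)
  n <- 150
  co <- data.frame(matrix(rnorm(n * 10), n))
  co$outcome <- rbinom(n, 1, stats::plogis(-0.8 + 0.5 * co$X1))
  model_fn <- function(dat) fit_logistic(
    as.matrix(dat[, paste0("X", 1:10)]), dat$outcome, retention_alpha = 1,
    terms = lapply(paste0("X", 1:10), function(p)
      list(name = p, source = p, transform = "identity",
           power = NA_real_, scale = NA_real_)))
  v1 <- bootstrap_validate(model_fn, co, b = 40, seed = 7)
  v2 <- bootstrap_validate(model_fn, co, b = 40, seed = 7)
  expect_identical(v1, v2)
  expect_lt(v1$corrected_c, v1$apparent_c)
  expect_lt(v1$shrinkage_factor, 1)
})

test_that("uniform shrinkage rescales slopes and recenters the intercept", {
  co <- make_test_cohort(4000, seed = 118)
  preds <- names(published_coefficients()$coefficients)
  fit <- fit_model_pipeline(co, predictors = preds, age_var = "age",
                            age_powers = c(2, 3), retention_alpha = 1)
  expect_identical(apply_shrinkage(fit, 1, co), fit)
  shrunk <- apply_shrinkage(fit, 0.926, co)
  expect_equal(shrunk$coefficients, fit$coefficients * 0.926)
  expect_equal(shrunk$shrinkage_factor, 0.926)
  # mean predicted probability equals observed prevalence after refit
  expect_equal(mean(predict_risk(shrunk, co)), mean(co$outcome),
               tolerance = 1e-8)
  # round-trip: unshrinking a shrunken coefficient recovers exp(original)
  expect_equal(unshrink_odds_ratio(shrunk$coefficients[["n_drugs"]], 0.926),
               exp(fit$coefficients[["n_drugs"]]), tolerance = 1e-12)
  expect_error(apply_shrinkage(fit, 0, co), "\\(0, 1\\]")
  expect_error(apply_shrinkage(fit, -0.5, co), "\\(0, 1\\]")
})

test_that("calibration curves track the diagonal under self-calibration", {
  set.seed(119)
  p <- stats::plogis(rnorm(20000, -1, 1))
  y <- rbinom(length(p), 1, p)
  cc <- calibration_curve(p, y)
  mid <- cc$curve$predicted > 0.05 & cc$curve$predicted < 0.8
  expect_lt(max(abs(cc$curve$observed[mid] - cc$curve$predicted[mid])),
            0.05)
  expect_equal(sum(cc$deciles$n), length(p))

  # deliberately inflated high predictions fall below the diagonal
  p_inf <- stats::plogis(stats::qlogis(p) + ifelse(p > 0.5, 1.5, 0))
  cc2 <- calibration_curve(p_inf, y)
  high <- cc2$curve$predicted > 0.7
  expect_true(mean(cc2$curve$observed[high] -
                     cc2$curve$predicted[high] < 0) > 0.9)
})
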