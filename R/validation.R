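#' Concordance (c-) statistic
#'
#' Probability that a randomly chosen event patient receives a higher
#' predicted probability than a randomly chosen non-event patient, ties
#' counted one half — the AUROC. Computed from midranks in O(n log n);
#' invariant under any strictly increasing transform of the probabilities.
#'
#' @param probabilities Numeric vector of predicted risks.
#' @param outcomes Binary 0/1 vector; both classes must be present.
#' @return A number in \[0, 1\].
#' @export
c_statistic <- function(probabilities, outcomes) {
  y <- as.numeric(outcomes)
  stopifnot(length(probabilities) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic recalibration: calibration intercept and slope
#'
#' Regresses the outcomes on the linear predictor `logit(p)`. The slope is
#' the coefficient of a logistic fit `outcome ~ lp`; the intercept is
#' calibration-in-the-large, estimated with the slope fixed at 1 (offset
#' fit). A slope below 1 indicates overfitting: predictions too extreme.
#'
#' @inheritParams c_statistic
#' @return List with `intercept` and `slope`.
#' @export
calibration_fit <- function(probabilities, outcomes) {
  y <- as.numeric(outcomes)
  stopifnot(all(y %in% c(0, 1)))
  lp <- stats::qlogis(pmin(pmax(probabilities, 1e-12), 1 - 1e-12))
  if (stats::sd(lp) < 1e-12) {
    stop("degenerate (constant) linear predictor", call. = FALSE)
  }
  slope_fit <- stats::glm.fit(cbind(1, lp), y, family = stats::binomial())
  int_fit <- stats::glm.fit(matrix(1, length(y)), y, offset = lp,
                            family = stats::binomial())
  list(intercept = unname(int_fit$coefficients[1]),
       slope = unname(slope_fit$coefficients[2]))
}

#' Bootstrap internal validation with optimism correction
#'
#' Harrell's procedure: for each of `b` bootstrap replicates, the entire
#' model-development procedure (`model_fn`) is re-run on a resample of the
#' cohort; the optimism of an index is the mean difference between the
#' bootstrap model's performance on its own bootstrap sample and on the
#' original cohort. Corrected index = apparent index − optimism. The
#' corrected calibration slope is the uniform shrinkage factor.
#'
#' @param model_fn Function `cohort -> fitted_model` re-running the full
#'   development pipeline (selection included) on the sample it is given.
#' @param cohort Cohort data frame with `outcome`.
#' @param b Number of bootstrap replicates (default 500).
#' @param seed Integer seed; replicate resamples derive from it.
#' @param index_fn Internal test hook: function `(replicate, n) -> integer
#'   indices` supplying the bootstrap indices; defaults to sampling with
#'   replacement.
#' @param max_failure_rate Replicates whose refit fails are dropped; above
#'   this fraction of failures the validation errors out.
#' @return An object of class `validation_report`: apparent and corrected
#'   c-statistic, calibration intercept and slope, the shrinkage factor
#'   (corrected slope), optimism components, `n_bootstrap` (effective) and
#'   `n_failed`.
#' @export
bootstrap_validate <- function(model_fn, cohort, b = 500, seed = 1L,
                               index_fn = NULL, max_failure_rate = 0.20) {
  stopifnot(b >= 1, "outcome" %in% names(cohort))
  n <- nrow(cohort)
  apparent_model <- model_fn(cohort)
  p_app <- predict_risk(apparent_model, cohort)
  apparent_c <- c_statistic(p_app, cohort$outcome)
  apparent_cal <- calibration_fit(p_app, cohort$outcome)

  set.seed(seed)
  idx_sets <- lapply(seq_len(b), function(i) {
    if (is.null(index_fn)) sample.int(n, n, replace = TRUE)
    else index_fn(i, n)
  })

  opt_c <- opt_slope <- opt_int <- rep(NA_real_, b)
  failed <- 0L
  for (i in seq_len(b)) {
    boot <- cohort[idx_sets[[i]], , drop = FALSE]
    fit_i <- tryCatch(model_fn(boot), error = function(e) NULL)
    if (is.null(fit_i)) {
      failed <- failed + 1L
      next
    }
    p_boot <- predict_risk(fit_i, boot)
    p_orig <- predict_risk(fit_i, cohort)
    c_boot <- c_statistic(p_boot, boot$outcome)
    c_orig <- c_statistic(p_orig, cohort$outcome)
    cal_boot <- tryCatch(calibration_fit(p_boot, boot$outcome),
                         error = function(e) NULL)
    cal_orig <- tryCatch(calibration_fit(p_orig, cohort$outcome),
                         error = function(e) NULL)
    if (is.null(cal_boot) || is.null(cal_orig)) {
      failed <- failed + 1L
      next
    }
    opt_c[i] <- c_boot - c_orig
    opt_slope[i] <- cal_boot$slope - cal_orig$slope
    opt_int[i] <- cal_boot$intercept - cal_orig$intercept
  }
  if (failed > max_failure_rate * b) {
    stop(failed, " of ", b, " bootstrap replicates failed to refit",
         call. = FALSE)
  }
  optimism_c <- mean(opt_c, na.rm = TRUE)
  optimism_slope <- mean(opt_slope, na.rm = TRUE)
  optimism_int <- mean(opt_int, na.rm = TRUE)
  structure(list(apparent_c = apparent_c,
                 corrected_c = apparent_c - optimism_c,
                 apparent_intercept = apparent_cal$intercept,
                 apparent_slope = apparent_cal$slope,
                 corrected_intercept = apparent_cal$intercept - optimism_int,
                 corrected_slope = apparent_cal$slope - optimism_slope,
                 shrinkage_factor = apparent_cal$slope - optimism_slope,
                 optimism_c = optimism_c,
                 optimism_slope = optimism_slope,
                 optimism_intercept = optimism_int,
                 n_bootstrap = b - failed,
                 n_failed = failed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Internal validation (bootstrap optimism correction)\n")
  cat(sprintf("  c-statistic: apparent %.3f, corrected %.3f\n",
              x$apparent_c, x$corrected_c))
  cat(sprintf("  calibration: apparent intercept %.3f / slope %.3f\n",
              x$apparent_intercept, x$apparent_slope))
  cat(sprintf("               corrected intercept %.3f / slope %.3f\n",
              x$corrected_intercept, x$corrected_slope))
  cat(sprintf("  uniform shrinkage factor: %.3f (%d replicates, %d failed)\n",
              x$shrinkage_factor, x$n_bootstrap, x$n_failed))
  invisible(x)
}

#' Apply a uniform shrinkage factor to a fitted model
#'
#' Multiplies every slope coefficient by `factor` and re-estimates the
#' intercept by refitting an intercept-only logistic model with the shrunken
#' linear predictor as offset, so the mean predicted probability equals the
#' observed prevalence on the fitting data (the maximum-likelihood score
#' identity).
#'
#' @param model A `fitted_model`.
#' @param factor Shrinkage factor in (0, 1\].
#' @param cohort The fitting cohort (with `outcome`), used to re-estimate the
#'   intercept.
#' @return The shrunken `fitted_model` with `shrinkage_factor` recorded.
#' @export
apply_shrinkage <- function(model, factor, cohort) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 ||
      factor > 1) {
    stop("shrinkage factor must lie in (0, 1]", call. = FALSE)
  }
  if (factor == 1) return(model)
  shrunk <- model
  shrunk$coefficients <- model$coefficients * factor
  X <- .model_design(shrunk, cohort)
  lp <- as.vector(X %*% shrunk$coefficients)
  refit <- stats::glm.fit(matrix(1, nrow(cohort)), cohort$outcome,
                          offset = lp, family = stats::binomial())
  shrunk$intercept <- unname(refit$coefficients[1])
  shrunk$shrinkage_factor <- model$shrinkage_factor * factor
  shrunk
}

#' Calibration curve: smoothed observed vs predicted risk
#'
#' Local-regression (loess) smooth of the binary outcome against predicted
#' probability on a probability grid, plus a decile-of-risk table of mean
#' predicted and observed event rates.
#'
#' @inheritParams c_statistic
#' @param span Loess span (default 0.75).
#' @param grid_size Number of grid points spanning the range of predictions.
#' @return List with `curve` (data frame `predicted`, `observed`) and
#'   `deciles` (data frame `decile`, `n`, `mean_predicted`, `observed_rate`).
#' @export
calibration_curve <- function(probabilities, outcomes, span = 0.75,
                              grid_size = 50L) {
  y <- as.numeric(outcomes)
  stopifnot(all(y %in% c(0, 1)))
  if (stats::sd(probabilities) < 1e-12) {
    stop("degenerate (constant) predictions", call. = FALSE)
  }
  fit <- stats::loess(y ~ probabilities, span = span,
                      degree = 1, family = "gaussian")
  grid <- seq(min(probabilities), max(probabilities), length.out = grid_size)
  curve <- data.frame(predicted = grid,
                      observed = pmin(pmax(stats::predict(fit, grid), 0), 1))
  qs <- stats::quantile(probabilities, probs = seq(0, 1, 0.1), type = 7)
  dec <- cut(probabilities, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  deciles <- do.call(rbind, lapply(sort(unique(dec)), function(d) {
    sel <- dec == d
    data.frame(decile = d, n = sum(sel),
               mean_predicted = mean(probabilities[sel]),
               observed_rate = mean(y[sel]))
  }))
  list(curve = curve, deciles = deciles)
}
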