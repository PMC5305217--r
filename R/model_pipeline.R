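#' Fractional-polynomial transforms of age
#'
#' Evaluates `(age/scale)^p` for each power `p`, with `p = 0` encoding the
#' natural logarithm, the usual fractional-polynomial convention. Age is
#' scaled (default divisor 100) before powering so coefficients stay on a
#' readable scale.
#'
#' @param age Numeric vector of ages in years (>= 0).
#' @param powers Numeric vector of powers from the fractional-polynomial set
#'   \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}.
#' @param scale Divisor applied before powering.
#' @return Matrix with one column per power, named `fp_age_<p>`.
#' @examples
#' fp_terms(75, c(2, 3))  # 0.5625, 0.421875
#' @export
fp_terms <- function(age, powers, scale = 100) {
  if (any(age < 0, na.rm = TRUE)) stop("age must be >= 0", call. = FALSE)
  x <- age / scale
  if (any(powers <= 0) && any(x <= 0, na.rm = TRUE)) {
    stop("log or negative powers are undefined at age 0", call. = FALSE)
  }
  out <- vapply(powers, function(p) if (p == 0) log(x) else x^p,
                numeric(length(x)))
  out <- matrix(out, nrow = length(x))
  colnames(out) <- paste0("fp_age_", .power_label(powers))
  out
}

.power_label <- function(powers) {
  vapply(powers, function(p) sub("-", "m", format(p)), character(1))
}

.fp_power_set <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# FP2 design for a power pair; a repeated power p contributes x^p and
# x^p * ln(x) per the fractional-polynomial convention.
.fp2_design <- function(age, p1, p2, scale = 100) {
  x <- age / scale
  one <- function(p) if (p == 0) log(x) else x^p
  if (p1 == p2) {
    m <- cbind(one(p1), one(p1) * log(x))
  } else {
    m <- cbind(one(p1), one(p2))
  }
  colnames(m) <- paste0("fp_age_", .power_label(c(p1, p2)),
                        c("", if (p1 == p2) ".log" else ""))
  m
}

.glm_with_trace <- function(X, y) {
  # capture the IRLS deviance trace so monotone convergence is inspectable
  # separation and non-convergence are diagnosed explicitly by the caller
  txt <- utils::capture.output(suppressWarnings(
    fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                          family = stats::binomial(),
                          control = stats::glm.control(trace = TRUE))))
  dev <- as.numeric(sub(".*Deviance = ([-0-9.eE+]+).*", "\\1",
                        grep("Deviance", txt, value = TRUE)))
  fit$deviance_trace <- dev
  fit
}

#' Fit a logistic model with permissive backward elimination
#'
#' Maximum-likelihood logistic regression followed by backward elimination:
#' while the largest Wald p-value among removable terms is at or above
#' `retention_alpha`, that term is dropped and the model refitted. The
#' retention threshold is deliberately large (default 0.30) so that weakly
#' informative predictors are kept for prediction rather than discarded on a
#' strict significance criterion.
#'
#' @param design Numeric matrix or data frame of predictor columns (no
#'   intercept column).
#' @param outcomes Binary 0/1 vector, one per row of `design`.
#' @param retention_alpha Wald p-value threshold for retention.
#' @param force_include Column names never removed regardless of p-value.
#' @param terms Optional list of term descriptors (see [fit_model_pipeline()]);
#'   carried into the fitted model for prediction and serialization.
#' @return An object of class `fitted_model`: `intercept`, `coefficients`,
#'   `se`, `p_values`, `terms`, `deviance`, `null_deviance`,
#'   `deviance_trace`, `iterations`, `converged`, `retention_alpha`,
#'   `shrinkage_factor` (1 until [apply_shrinkage()]), `n`, `dropped`.
#' @export
fit_logistic <- function(design, outcomes, retention_alpha = 0.30,
                         force_include = character(0), terms = NULL) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(outcomes)
  stopifnot(all(y %in% c(0, 1)))
  if (nrow(X) <= ncol(X) + 1) {
    stop("more terms than observations support", call. = FALSE)
  }
  const <- apply(X, 2, function(col) length(unique(col)) < 2L)
  if (any(const)) {
    stop("constant design column(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  qr_rank <- qr(cbind(1, X))$rank
  if (qr_rank < ncol(X) + 1L) {
    stop("rank-deficient design (aliased columns present)", call. = FALSE)
  }

  dropped <- character(0)
  repeat {
    fit <- .glm_with_trace(X, y)
    coefs <- fit$coefficients
    if (any(is.na(coefs))) {
      stop("aliased term(s): ",
           paste(names(coefs)[is.na(coefs)], collapse = ", "), call. = FALSE)
    }
    if (length(coefs) > 1 && max(abs(coefs[-1])) > 20) {
      stop("possible complete separation driven by term `",
           names(which.max(abs(coefs[-1]))), "`", call. = FALSE)
    }
    if (!fit$converged) {
      stop("logistic fit failed to converge after ", fit$iter, " iterations",
           call. = FALSE)
    }
    # Wald p-values from the final IRLS weights
    w <- fit$weights
    XtWX <- crossprod(cbind(1, X) * sqrt(w))
    se <- sqrt(diag(solve(XtWX)))
    z <- coefs / se
    p <- 2 * stats::pnorm(-abs(z))
    names(se) <- names(p) <- names(coefs)

    removable <- setdiff(colnames(X), force_include)
    p_rem <- p[removable]
    if (length(p_rem) == 0 || max(p_rem) < retention_alpha) break
    worst <- names(which.max(p_rem))
    dropped <- c(dropped, worst)
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }

  kept <- colnames(X)
  if (!is.null(terms)) {
    terms <- terms[vapply(terms, function(t) t$name %in% kept, logical(1))]
  }
  null_dev <- -2 * sum(stats::dbinom(y, 1, mean(y), log = TRUE))
  structure(list(intercept = unname(fit$coefficients[1]),
                 coefficients = fit$coefficients[-1],
                 se = se[-1], intercept_se = unname(se[1]),
                 p_values = p[-1],
                 terms = terms,
                 deviance = fit$deviance,
                 null_deviance = null_dev,
                 deviance_trace = fit$deviance_trace,
                 iterations = fit$iter,
                 converged = fit$converged,
                 retention_alpha = retention_alpha,
                 shrinkage_factor = 1,
                 n = length(y),
                 dropped = dropped),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("Logistic model (n = %d, deviance = %.2f)\n", x$n, x$deviance))
  cat(sprintf("  intercept  % .4f\n", x$intercept))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-34s % .4f  (p = %.3g)\n", nm, x$coefficients[[nm]],
                x$p_values[[nm]]))
  }
  if (x$shrinkage_factor != 1) {
    cat(sprintf("  uniform shrinkage factor %.3f applied\n",
                x$shrinkage_factor))
  }
  if (length(x$dropped)) {
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select fractional-polynomial powers for age
#'
#' Finds the deviance-best second-degree fractional polynomial (FP2) of
#' scaled age over the power set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} — 28
#' distinct pairs plus 8 repeated-power pairs — adjusting for a fixed set of
#' other terms, then applies the standard closed test: FP2 vs no age effect
#' (4 df), FP2 vs linear (3 df), FP2 vs best FP1 (2 df), each at `alpha`,
#' stopping at the first non-significant comparison.
#'
#' @param age Numeric vector of ages (> 0 so log powers are defined).
#' @param fixed_design Matrix/data frame of adjustment terms (may have zero
#'   columns).
#' @param outcomes Binary 0/1 vector.
#' @param alpha Closed-test significance level (default 0.05).
#' @param scale Age divisor before powering.
#' @return List: `type` (`"null"`, `"linear"`, `"fp1"` or `"fp2"`),
#'   `powers` (numeric, empty for null), `deviance` of the selected age
#'   model, and `closed_test` (the three comparison p-values).
#' @export
select_fp <- function(age, fixed_design, outcomes, alpha = 0.05,
                      scale = 100) {
  F <- if (is.null(fixed_design) || NCOL(fixed_design) == 0) {
    matrix(numeric(0), nrow = length(age), ncol = 0)
  } else as.matrix(fixed_design)
  y <- as.numeric(outcomes)
  dev_of <- function(A) {
    X <- cbind(1, F, A)
    # extreme candidate powers can saturate fitted probabilities; that only
    # penalizes their deviance, so the search proceeds quietly
    suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial())$deviance)
  }
  dev_null <- dev_of(NULL)
  dev_linear <- dev_of(fp_terms(age, 1, scale))

  fp1 <- lapply(.fp_power_set, function(p)
    list(powers = p, dev = dev_of(fp_terms(age, p, scale))))
  best_fp1 <- fp1[[which.min(vapply(fp1, `[[`, numeric(1), "dev"))]]

  pairs <- list()
  for (i in seq_along(.fp_power_set)) {
    for (j in i:length(.fp_power_set)) {
      pairs[[length(pairs) + 1L]] <- c(.fp_power_set[i], .fp_power_set[j])
    }
  }
  fp2 <- lapply(pairs, function(pp)
    list(powers = pp, dev = dev_of(.fp2_design(age, pp[1], pp[2], scale))))
  best_fp2 <- fp2[[which.min(vapply(fp2, `[[`, numeric(1), "dev"))]]

  p_any <- stats::pchisq(dev_null - best_fp2$dev, df = 4, lower.tail = FALSE)
  p_nonlin <- stats::pchisq(dev_linear - best_fp2$dev, df = 3,
                            lower.tail = FALSE)
  p_fp2 <- stats::pchisq(best_fp1$dev - best_fp2$dev, df = 2,
                         lower.tail = FALSE)
  closed <- c(any_effect = p_any, nonlinearity = p_nonlin, fp2_vs_fp1 = p_fp2)

  if (p_any >= alpha) {
    list(type = "null", powers = numeric(0), deviance = dev_null,
         closed_test = closed)
  } else if (p_nonlin >= alpha) {
    list(type = "linear", powers = 1, deviance = dev_linear,
         closed_test = closed)
  } else if (p_fp2 >= alpha) {
    list(type = "fp1", powers = best_fp1$powers, deviance = best_fp1$dev,
         closed_test = closed)
  } else {
    list(type = "fp2", powers = best_fp2$powers, deviance = best_fp2$dev,
         closed_test = closed)
  }
}

#' Fit the full risk-model pipeline on a cohort
#'
#' Orchestrates model development on a cohort carrying the binary `outcome`:
#' fractional-polynomial selection for age (optional; powers may be fixed),
#' then multivariable logistic regression over the remaining predictors with
#' permissive backward elimination. Age terms selected by the closed test are
#' always retained (they enter as a block).
#'
#' @param cohort Cohort data frame with `outcome` and all predictor columns.
#' @param predictors Character vector of predictor columns besides age.
#' @param age_var Name of the age column, or `NULL` for no age terms.
#' @param age_powers Fixed fractional-polynomial powers for age; `NULL`
#'   (default) runs [select_fp()].
#' @param fp_alpha Closed-test level for FP selection.
#' @param retention_alpha Backward-elimination threshold.
#' @param force_include Predictors never eliminated.
#' @param age_scale Age divisor before powering.
#' @return A `fitted_model` whose `terms` metadata records each design
#'   column's source and transform, sufficient for [predict_risk()] and
#'   serialization.
#' @export
fit_model_pipeline <- function(cohort, predictors, age_var = "age",
                               age_powers = NULL, fp_alpha = 0.05,
                               retention_alpha = 0.30,
                               force_include = character(0),
                               age_scale = 100) {
  stopifnot("outcome" %in% names(cohort))
  missing_cols <- setdiff(c(predictors, age_var), names(cohort))
  if (length(missing_cols)) {
    stop("predictor column(s) absent from cohort: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- cohort$outcome
  base <- as.matrix(cohort[, predictors, drop = FALSE])
  terms <- lapply(predictors, function(p)
    list(name = p, source = p, transform = "identity", power = NA_real_,
         scale = NA_real_))

  age_cols <- NULL
  if (!is.null(age_var)) {
    if (is.null(age_powers)) {
      sel <- select_fp(cohort[[age_var]], base, y, alpha = fp_alpha,
                       scale = age_scale)
      age_powers <- sel$powers
    }
    if (length(age_powers) > 0) {
      if (length(age_powers) == 2 && age_powers[1] == age_powers[2]) {
        age_cols <- .fp2_design(cohort[[age_var]], age_powers[1],
                                age_powers[2], age_scale)
        tr <- c("fractional_power", "fractional_power_log")
      } else {
        age_cols <- fp_terms(cohort[[age_var]], age_powers, age_scale)
        tr <- rep("fractional_power", length(age_powers))
      }
      terms <- c(terms, lapply(seq_along(age_powers), function(k)
        list(name = colnames(age_cols)[k], source = age_var,
             transform = tr[k], power = age_powers[k], scale = age_scale)))
    }
  }

  design <- cbind(base, age_cols)
  fit_logistic(design, y, retention_alpha = retention_alpha,
               force_include = c(force_include, colnames(age_cols)),
               terms = terms)
}

# Rebuild the design matrix a fitted model expects from cohort columns.
.model_design <- function(model, cohort) {
  cols <- lapply(model$terms, function(t) {
    src <- cohort[[t$source]]
    if (is.null(src)) {
      stop("cohort lacks column `", t$source, "` required by the model",
           call. = FALSE)
    }
    switch(t$transform,
           identity = as.numeric(src),
           fractional_power = {
             x <- src / t$scale
             if (t$power == 0) log(x) else x^t$power
           },
           fractional_power_log = {
             x <- src / t$scale
             (if (t$power == 0) log(x) else x^t$power) * log(x)
           },
           stop("unknown transform: ", t$transform, call. = FALSE))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(model$terms, `[[`, character(1), "name")
  m[, names(model$coefficients), drop = FALSE]
}

#' Predicted probabilities from a fitted model
#'
#' @param model A `fitted_model`.
#' @param cohort Cohort data frame with the model's source columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_risk <- function(model, cohort) {
  stopifnot(inherits(model, "fitted_model"))
  X <- .model_design(model, cohort)
  stats::plogis(model$intercept + as.vector(X %*% model$coefficients))
}

#' Serialize / deserialize a fitted model as a JSON document
#'
#' Versioned JSON document: intercept, per-term name/source/transform/power/
#' scale/coefficient, shrinkage factor and fitting metadata.
#'
#' @param model A `fitted_model`.
#' @param path File path.
#' @return `model_to_json` returns `path` invisibly; `model_from_json` a
#'   `fitted_model`.
#' @export
model_to_json <- function(model, path) {
  doc <- list(format = "mederrisk-model", version = 1L,
              intercept = model$intercept,
              shrinkage_factor = model$shrinkage_factor,
              retention_alpha = model$retention_alpha,
              n = model$n,
              terms = lapply(names(model$coefficients), function(nm) {
                t <- model$terms[[which(vapply(model$terms, `[[`,
                                               character(1), "name") == nm)]]
                c(list(name = nm, source = t$source,
                       transform = t$transform),
                  if (!is.na(t$power)) list(power = t$power),
                  if (!is.na(t$scale)) list(scale = t$scale),
                  list(coefficient = unname(model$coefficients[[nm]])))
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::read_json(path)
  coefs <- vapply(doc$terms, function(t) t$coefficient, numeric(1))
  names(coefs) <- vapply(doc$terms, function(t) t$name, character(1))
  null_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  terms <- lapply(doc$terms, function(t)
    list(name = t$name, source = t$source, transform = t$transform,
         power = null_na(t$power), scale = null_na(t$scale)))
  structure(list(intercept = doc$intercept, coefficients = coefs,
                 terms = terms,
                 shrinkage_factor = doc$shrinkage_factor,
                 retention_alpha = doc$retention_alpha,
                 n = doc$n, dropped = character(0)),
            class = "fitted_model")
}
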