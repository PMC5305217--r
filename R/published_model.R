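#' The frozen published risk coefficients
#'
#' The package's reference model for clinically significant in-hospital
#' medication errors: a logistic model on eleven admission-time predictors
#' with a second-degree fractional polynomial of age. The stored log-odds
#' ratios are the corrected values, i.e. the original maximum-likelihood
#' estimates multiplied by a uniform shrinkage factor of 0.926; probabilities
#' are computed with these corrected coefficients. The curve of the two age
#' terms, 7.07·(age/100)² − 6.26·(age/100)³, is n-shaped with maximal risk
#' around 75 years.
#'
#' @return A list: `intercept` (−3.83), `age_powers` (2, 3),
#'   `age_coefficients` (7.07, −6.26), `age_scale` (100), `coefficients`
#'   (named corrected log-odds ratios of the nine non-age predictors) and
#'   `shrinkage` (0.926).
#' @export
published_coefficients <- function() {
  list(intercept = -3.83,
       age_powers = c(2, 3),
       age_coefficients = c(7.07, -6.26),
       age_scale = 100,
       coefficients = c(
         n_drugs                              =  0.14,
         treatment_initiated_before_admission =  1.60,
         bpmh_available                       = -0.64,
         atc_N05                              =  0.31,
         atc_B05                              = -0.16,
         surgical_admission                   =  0.29,
         prior_hospitalization_30d            = -0.36,
         admission_from_ed                    =  0.27,
         night_admission                      = -0.18,
         admission_from_outside               = -0.51),
       shrinkage = 0.926)
}

#' Predicted probability of a clinically significant medication error
#'
#' Exact evaluation of the published formula
#' `p = 1 / (1 + exp(-(intercept + sum(w_i * logOR_i))))` with the corrected
#' (shrunken) coefficients. Vectorized over the rows of `patients`. Every
#' predictor column must be present; missing fields raise an error naming
#' them — there is no silent imputation.
#'
#' @param patients Data frame with columns `age`, `n_drugs` and the nine
#'   binary predictor flags named as in [published_coefficients()].
#' @return Numeric vector of probabilities strictly in (0, 1).
#' @examples
#' pat <- data.frame(age = 75, n_drugs = 5,
#'                   treatment_initiated_before_admission = 1,
#'                   bpmh_available = 0, atc_N05 = 0, atc_B05 = 0,
#'                   surgical_admission = 0, prior_hospitalization_30d = 0,
#'                   admission_from_ed = 0, night_admission = 0,
#'                   admission_from_outside = 0)
#' predict_probability(pat)  # ~0.452
#' @export
predict_probability <- function(patients) {
  pc <- published_coefficients()
  needed <- c("age", names(pc$coefficients))
  missing_cols <- setdiff(needed, names(patients))
  if (length(missing_cols) > 0) {
    stop("missing predictor field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(patients[, needed]))) {
    stop("missing values in predictor fields; no imputation is performed",
         call. = FALSE)
  }
  fp <- fp_terms(patients$age, pc$age_powers, scale = pc$age_scale)
  lp <- pc$intercept + as.vector(fp %*% pc$age_coefficients)
  for (nm in names(pc$coefficients)) {
    lp <- lp + pc$coefficients[[nm]] * patients[[nm]]
  }
  stats::plogis(lp)
}

#' Reconstruct the uncorrected odds ratio from a corrected log-odds ratio
#'
#' The published table stores log-odds ratios after multiplication by the
#' uniform shrinkage factor while its odds-ratio column shows the original
#' (uncorrected) estimates; dividing the corrected log-odds ratio by the
#' shrinkage factor and exponentiating recovers that column.
#'
#' @param corrected_logor Corrected (shrunken) log-odds ratio.
#' @param shrinkage Uniform shrinkage factor in (0, 1\].
#' @return The uncorrected odds ratio `exp(corrected_logor / shrinkage)`.
#' @examples
#' round(unshrink_odds_ratio(0.14), 2)   # 1.16 per additional drug
#' round(unshrink_odds_ratio(-0.64), 2)  # 0.50 for an available BPMH
#' @export
unshrink_odds_ratio <- function(corrected_logor, shrinkage = 0.926) {
  if (any(shrinkage <= 0) || any(shrinkage > 1)) {
    stop("shrinkage must lie in (0, 1]", call. = FALSE)
  }
  exp(corrected_logor / shrinkage)
}

#' Age-risk profile of the published model
#'
#' The age effect `b2 (age/100)^2 + b3 (age/100)^3` with `b3 < 0` is
#' n-shaped: odds of a significant medication error rise to a maximum at
#' `age* = 100 * 2 b2 / (3 |b3|)` and decline thereafter. The peak odds
#' ratio (relative to the age-zero reference, where both terms vanish) is
#' computed from the unshrunk coefficients, i.e. the corrected values divided
#' by the shrinkage factor.
#'
#' @param ages Grid of ages (years) for the returned curve.
#' @return List: `peak_age_years` (exact), `peak_age_rounded`,
#'   `peak_odds_ratio` and `curve` (data frame `age`, `odds_ratio` on the
#'   unshrunk scale).
#' @export
age_risk_profile <- function(ages = 18:100) {
  pc <- published_coefficients()
  b2 <- pc$age_coefficients[1] / pc$shrinkage
  b3 <- pc$age_coefficients[2] / pc$shrinkage
  a_star <- 2 * b2 / (3 * abs(b3))
  effect <- function(a) b2 * a^2 + b3 * a^3
  list(peak_age_years = a_star * pc$age_scale,
       peak_age_rounded = round(a_star * pc$age_scale),
       peak_odds_ratio = exp(effect(a_star)),
       curve = data.frame(age = ages,
                          odds_ratio = exp(effect(ages / pc$age_scale))))
}

#' Score a cohort CSV with the published model
#'
#' Reads a cohort CSV, appends a `predicted_probability` column computed with
#' [predict_probability()] and writes it back out.
#'
#' @param input Path to a cohort CSV.
#' @param output Path for the scored CSV.
#' @return The scored data frame, invisibly.
#' @export
score_cohort_file <- function(input, output) {
  cohort <- utils::read.csv(input)
  cohort$predicted_probability <- predict_probability(cohort)
  utils::write.csv(cohort, output, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}
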