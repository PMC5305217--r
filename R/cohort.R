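#' Specification of a synthetic inpatient cohort
#'
#' Builds a validated specification from which [generate_cohort()] draws a
#' reproducible synthetic cohort of adult hospital admissions. The defaults
#' emulate the marginal distributions of a 1,408-patient adult inpatient
#' cohort: median age 68 (IQR 57-80), 52.4% male, a right-skewed prescribed
#' drug count with median 1, and the tabulated prevalences of the
#' admission-circumstance covariates. The default drug-count and ATC-class
#' parameters were calibrated once by simulation so that, under the package's
#' published risk coefficients (see [published_coefficients()]), the mean
#' outcome probability is approximately 25.9%; they are frozen as package
#' defaults.
#'
#' @param n_patients Number of admissions to generate (non-negative integer).
#' @param seed Integer seed; every random draw in [generate_cohort()] flows
#'   from it.
#' @param age_distribution List with elements `mean`, `sd`, `min`, `max`
#'   describing a truncated normal age distribution in years. The default
#'   (mean 69, sd 17.5, truncated to \[18, 105\]) matches median 68 and
#'   IQR 57-80.
#' @param covariate_prevalences Named numeric vector of Bernoulli
#'   probabilities for the binary covariates (see Details for names).
#' @param drug_count_distribution List with elements `zero_prob`, `mu`,
#'   `size`: a zero-inflated negative binomial for the number of prescribed
#'   drugs.
#' @param atc_class_probabilities Named numeric vector of per-class
#'   prescription probabilities for the ATC drug-class indicator columns.
#'
#' @details
#' Binary covariates and their default prevalences (proportions observed in
#' the emulated cohort where available):
#' `male` 0.524, `treatment_initiated_before_admission` 0.9219,
#' `bpmh_available` 0.5483, `prior_hospitalization_30d` 0.1172,
#' `transfer_within_72h` 0.0241, `admission_from_ed` 0.1335,
#' `admission_from_outside` 0.0220, `night_admission` 0.1776,
#' `weekend_admission` 0.0923, `surgical_admission` 0.2521.
#'
#' Covariates are generated independently; the joint structure of a real
#' cohort is not modelled.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [assign_outcomes()]
#' @export
cohort_spec <- function(n_patients,
                        seed = 1L,
                        age_distribution = list(mean = 69, sd = 17.5,
                                                min = 18, max = 105),
                        covariate_prevalences = default_covariate_prevalences(),
                        drug_count_distribution = list(zero_prob = 0.25,
                                                       mu = 2.9, size = 1.2),
                        atc_class_probabilities = default_atc_probabilities()) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0 ||
      n_patients != floor(n_patients)) {
    stop("`n_patients` must be a single non-negative integer", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  .check_probs(covariate_prevalences, "covariate_prevalences")
  .check_probs(atc_class_probabilities, "atc_class_probabilities")
  if (drug_count_distribution$zero_prob < 0 ||
      drug_count_distribution$zero_prob > 1) {
    stop("drug-count zero_prob must be in [0,1]", call. = FALSE)
  }
  if (drug_count_distribution$mu < 0 || drug_count_distribution$size <= 0) {
    stop("drug-count mu must be >= 0 and size > 0", call. = FALSE)
  }
  if (age_distribution$min < 18) {
    stop("ages below 18 are outside the adult-inpatient scope", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 age_distribution = age_distribution,
                 covariate_prevalences = covariate_prevalences,
                 drug_count_distribution = drug_count_distribution,
                 atc_class_probabilities = atc_class_probabilities),
            class = "cohort_spec")
}

.check_probs <- function(p, what) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop(sprintf("`%s` must be a named vector", what), call. = FALSE)
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("all `%s` must be probabilities in [0,1]", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Default prevalences of the binary admission covariates
#'
#' @return Named numeric vector of probabilities.
#' @export
default_covariate_prevalences <- function() {
  c(male                                 = 738 / 1408,
    treatment_initiated_before_admission = 1298 / 1408,
    bpmh_available                       = 772 / 1408,
    prior_hospitalization_30d            = 165 / 1408,
    transfer_within_72h                  = 34 / 1408,
    admission_from_ed                    = 188 / 1408,
    admission_from_outside               = 31 / 1408,
    night_admission                      = 250 / 1408,
    weekend_admission                    = 130 / 1408,
    surgical_admission                   = 355 / 1408)
}

#' Default ATC drug-class prescription probabilities
#'
#' Prevalences of the five screened Anatomical Therapeutic Chemical classes:
#' antithrombotics (B01), systemic antibacterials (J01), psycholeptics (N05),
#' blood substitutes and perfusion solutions (B05) and analgesics (N02).
#' Chosen as plausible adult-inpatient values; class prevalences are not
#' tabulated in the emulated cohort.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_atc_probabilities <- function() {
  c(atc_B01 = 0.35, atc_J01 = 0.25, atc_N05 = 0.30,
    atc_B05 = 0.25, atc_N02 = 0.40)
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n_patients` admissions with independent covariates: truncated
#' normal age, Bernoulli binary covariates, zero-inflated negative binomial
#' drug count and Bernoulli ATC-class indicators. Identical specs (including
#' the seed) give bit-identical tables.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per admission: `patient_id`, `age`,
#'   `n_drugs`, the binary covariates and the ATC indicator columns. No
#'   outcome column; see [assign_outcomes()].
#' @examples
#' cohort <- generate_cohort(cohort_spec(100, seed = 42))
#' median(cohort$age)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be created by cohort_spec()", call. = FALSE)
  }
  n <- spec$n_patients
  cols <- list(patient_id = integer(0), age = numeric(0),
               n_drugs = integer(0))
  if (n == 0L) {
    out <- as.data.frame(cols)
    for (nm in names(spec$covariate_prevalences)) out[[nm]] <- integer(0)
    for (nm in names(spec$atc_class_probabilities)) out[[nm]] <- integer(0)
    return(out)
  }
  set.seed(spec$seed)
  ad <- spec$age_distribution
  lo <- stats::pnorm(ad$min, ad$mean, ad$sd)
  hi <- stats::pnorm(ad$max, ad$mean, ad$sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), ad$mean, ad$sd)
  dd <- spec$drug_count_distribution
  zero <- stats::rbinom(n, 1L, dd$zero_prob)
  n_drugs <- ifelse(zero == 1L, 0L,
                    stats::rnbinom(n, size = dd$size, mu = dd$mu))
  out <- data.frame(patient_id = seq_len(n), age = age,
                    n_drugs = as.integer(n_drugs))
  for (nm in names(spec$covariate_prevalences)) {
    out[[nm]] <- stats::rbinom(n, 1L, spec$covariate_prevalences[[nm]])
  }
  for (nm in names(spec$atc_class_probabilities)) {
    out[[nm]] <- stats::rbinom(n, 1L, spec$atc_class_probabilities[[nm]])
  }
  out
}

#' Define a true outcome model for synthetic data
#'
#' A logistic model on cohort columns used to generate outcomes. Age enters
#' through fractional-polynomial terms `(age/scale)^p`; every other named
#' coefficient multiplies the cohort column of the same name.
#'
#' @param intercept Log-odds intercept.
#' @param coefficients Named numeric vector of log-odds ratios; names must be
#'   cohort columns (e.g. `n_drugs`, `bpmh_available`, `atc_N05`).
#' @param age_powers Numeric vector of fractional-polynomial powers applied to
#'   scaled age (0 encodes the natural log).
#' @param age_coefficients Log-odds ratios, one per element of `age_powers`.
#' @param age_scale Divisor applied to age before powering (default 100).
#' @return An object of class `true_outcome_model`.
#' @export
true_outcome_model <- function(intercept, coefficients,
                               age_powers = numeric(0),
                               age_coefficients = numeric(0),
                               age_scale = 100) {
  stopifnot(length(age_powers) == length(age_coefficients))
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 age_powers = age_powers,
                 age_coefficients = age_coefficients,
                 age_scale = age_scale),
            class = "true_outcome_model")
}

#' The published coefficients as a true outcome model
#'
#' Convenience wrapper turning the frozen published risk coefficients into a
#' [true_outcome_model()] so synthetic outcomes can be generated from them.
#'
#' @return A `true_outcome_model`.
#' @export
published_true_model <- function() {
  pc <- published_coefficients()
  true_outcome_model(intercept = pc$intercept,
                     coefficients = pc$coefficients,
                     age_powers = pc$age_powers,
                     age_coefficients = pc$age_coefficients,
                     age_scale = pc$age_scale)
}

#' Linear predictor of a true outcome model on a cohort
#'
#' @param cohort Cohort data frame.
#' @param model A [true_outcome_model()].
#' @return Numeric vector of log-odds, one per row.
#' @export
linear_predictor <- function(cohort, model) {
  stopifnot(inherits(model, "true_outcome_model"))
  missing_cols <- setdiff(names(model$coefficients), names(cohort))
  if (length(missing_cols) > 0) {
    stop("model terms missing from cohort: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lp <- rep(model$intercept, nrow(cohort))
  if (length(model$age_powers) > 0) {
    fp <- fp_terms(cohort$age, model$age_powers, scale = model$age_scale)
    lp <- lp + as.vector(fp %*% model$age_coefficients)
  }
  for (nm in names(model$coefficients)) {
    lp <- lp + model$coefficients[[nm]] * cohort[[nm]]
  }
  lp
}

#' Assign binary outcomes from a true logistic model
#'
#' Draws `outcome ~ Bernoulli(plogis(lp_i))` per patient, where `lp` is the
#' model's linear predictor, with seeded reproducibility.
#'
#' @param cohort Cohort data frame.
#' @param model A [true_outcome_model()].
#' @param seed Integer seed for the Bernoulli draws.
#' @return The cohort with columns `true_p` (the generating probability) and
#'   binary `outcome` appended.
#' @export
assign_outcomes <- function(cohort, model, seed = 1L) {
  p <- stats::plogis(linear_predictor(cohort, model))
  set.seed(seed)
  cohort$true_p <- p
  cohort$outcome <- stats::rbinom(nrow(cohort), 1L, p)
  cohort
}

#' Generate medication-error records for a cohort with outcomes
#'
#' Companion fixture generator for severity-grading workflows: every patient
#' with `outcome == 1` receives at least one clinically significant
#' medication-error record (severity D or above); additional significant
#' records and harmless category-C records are sprinkled so the per-record
#' severity mix follows `severity_probs`. Hospitalization days are drawn from
#' a geometric distribution with mode at day 1.
#'
#' @param cohort Cohort with an `outcome` column.
#' @param seed Integer seed.
#' @param severity_probs Named probabilities over severities for significant
#'   records (`D`, `E+`, `H`) conditional on being significant; defaults are
#'   the observed proportions 315/475, 157/475, 3/475.
#' @param c_rate Expected number of harmless category-C records per patient.
#' @param extra_rate Expected number of significant records per positive
#'   patient beyond the first.
#' @param day_prob Success probability of the geometric day distribution.
#' @return Data frame with columns `patient_id`, `severity`
#'   (one of `"C"`, `"D"`, `"E+"`, `"H"`) and `day`.
#' @export
generate_me_records <- function(cohort, seed = 1L,
                                severity_probs = c(D = 315 / 475,
                                                   `E+` = 157 / 475,
                                                   H = 3 / 475),
                                c_rate = 0.095,
                                extra_rate = 0.30,
                                day_prob = 0.45) {
  if (!"outcome" %in% names(cohort)) {
    stop("cohort must carry an `outcome` column", call. = FALSE)
  }
  set.seed(seed)
  pos <- cohort$patient_id[cohort$outcome == 1L]
  n_sig <- if (length(pos)) 1L + stats::rpois(length(pos), extra_rate) else integer(0)
  sig_ids <- rep(pos, n_sig)
  sig_sev <- sample(names(severity_probs), length(sig_ids), replace = TRUE,
                    prob = severity_probs)
  n_c <- stats::rpois(nrow(cohort), c_rate)
  c_ids <- rep(cohort$patient_id, n_c)
  ids <- c(sig_ids, c_ids)
  sev <- c(sig_sev, rep("C", length(c_ids)))
  day <- 1L + stats::rgeom(length(ids), day_prob)
  out <- data.frame(patient_id = ids, severity = sev, day = as.integer(day),
                    stringsAsFactors = FALSE)
  out[order(out$patient_id, out$day), , drop = FALSE]
}

#' Write / read a cohort as headered CSV
#'
#' RFC-4180 CSV with a header row is the package's single tabular interchange
#' format.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
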