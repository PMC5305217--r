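#' Configuration of the predictor-screening stage
#'
#' @param eligibility_alpha Univariate p-value threshold below which a
#'   variable is eligible for the multivariable model. Deliberately permissive
#'   (default 0.50) so weakly informative predictors are not discarded before
#'   multivariable modelling.
#' @param min_support Minimal support of an association rule: the probability
#'   that antecedent drug classes and the endpoint co-occur (default 0.05).
#' @param min_confidence Minimal confidence: the probability of the endpoint
#'   given the antecedent classes (default 0.10).
#' @param max_antecedent Largest antecedent size enumerated (default 2);
#'   enumeration is exact.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(eligibility_alpha = 0.50,
                             min_support = 0.05,
                             min_confidence = 0.10,
                             max_antecedent = 2L) {
  vals <- c(eligibility_alpha, min_support, min_confidence)
  if (any(vals <= 0) || any(vals > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(max_antecedent >= 1)
  structure(list(eligibility_alpha = eligibility_alpha,
                 min_support = min_support,
                 min_confidence = min_confidence,
                 max_antecedent = as.integer(max_antecedent)),
            class = "screening_config")
}

#' Univariate eligibility screen of one candidate predictor
#'
#' Tests the association between a single variable and the binary outcome:
#' Wilcoxon-Mann-Whitney (normal approximation with tie correction) for
#' continuous variables, chi-square with Yates continuity correction for
#' binary ones. A variable is eligible when its p-value falls below
#' `config$eligibility_alpha`.
#'
#' @param cohort Cohort data frame with an `outcome` column.
#' @param variable Name of the column to screen.
#' @param type `"auto"` (binary iff the column takes only values 0/1),
#'   `"binary"` or `"continuous"`.
#' @param config A [screening_config()].
#' @return List with `variable`, `test`, `p_value` and `eligible`. A constant
#'   variable yields `p_value = NA`, `eligible = FALSE` and a warning.
#' @examples
#' # 2x2 table male/female x no/yes reproducing a Yates-corrected p of 0.119
#' cohort <- data.frame(
#'   male = rep(c(1, 0), c(738, 670)),
#'   outcome = c(rep(c(0, 1), c(560, 178)), rep(c(0, 1), c(483, 187))))
#' univariate_screen(cohort, "male")$p_value
#' @export
univariate_screen <- function(cohort, variable, type = c("auto", "binary",
                                                         "continuous"),
                              config = screening_config()) {
  type <- match.arg(type)
  if (!variable %in% names(cohort)) {
    stop("variable not found in cohort: ", variable, call. = FALSE)
  }
  if (!"outcome" %in% names(cohort)) {
    stop("cohort must carry an `outcome` column", call. = FALSE)
  }
  x <- cohort[[variable]]
  y <- cohort$outcome
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L) {
    warning("variable `", variable, "` is constant; excluded from screening",
            call. = FALSE)
    return(list(variable = variable, test = NA_character_,
                p_value = NA_real_, eligible = FALSE))
  }
  if (type == "auto") {
    type <- if (all(x %in% c(0, 1))) "binary" else "continuous"
  }
  if (type == "binary") {
    tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
    p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
    test <- "chi-square (Yates)"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x ~ y, exact = FALSE, correct = TRUE)$p.value)
    test <- "Wilcoxon-Mann-Whitney"
  }
  list(variable = variable, test = test, p_value = p,
       eligible = is.finite(p) && p < config$eligibility_alpha)
}

#' Screen a set of candidate predictors
#'
#' Applies [univariate_screen()] to each variable and assembles the screening
#' report the pipeline writes as CSV.
#'
#' @inheritParams univariate_screen
#' @param variables Character vector of column names; defaults to every
#'   column except `patient_id`, `outcome` and `true_p`.
#' @return Data frame with columns `variable`, `test`, `p_value`, `eligible`.
#' @export
screen_predictors <- function(cohort, variables = NULL,
                              config = screening_config()) {
  if (is.null(variables)) {
    variables <- setdiff(names(cohort), c("patient_id", "outcome", "true_p"))
  }
  rows <- lapply(variables, function(v)
    univariate_screen(cohort, v, config = config))
  data.frame(variable = vapply(rows, `[[`, character(1), "variable"),
             test = vapply(rows, `[[`, character(1), "test"),
             p_value = vapply(rows, `[[`, numeric(1), "p_value"),
             eligible = vapply(rows, `[[`, logical(1), "eligible"),
             stringsAsFactors = FALSE)
}

#' Build per-patient transactions from ATC indicator columns
#'
#' Each patient becomes a set of ATC class labels; patients with
#' `outcome == 1` additionally carry the endpoint label, the fixed rule
#' consequent.
#'
#' @param cohort Cohort with ATC indicator columns (prefix `atc_`) and an
#'   `outcome` column.
#' @param classes Indicator columns to use; defaults to every `atc_*` column.
#' @param endpoint_label Label marking endpoint-positive transactions.
#' @return List of character vectors, one per patient.
#' @export
atc_transactions <- function(cohort, classes = NULL,
                             endpoint_label = "significant_me") {
  if (is.null(classes)) classes <- grep("^atc_", names(cohort), value = TRUE)
  if (!"outcome" %in% names(cohort)) {
    stop("cohort must carry an `outcome` column", call. = FALSE)
  }
  lapply(seq_len(nrow(cohort)), function(i) {
    items <- classes[vapply(classes, function(cl) cohort[[cl]][i] == 1,
                            logical(1))]
    if (cohort$outcome[i] == 1) items <- c(items, endpoint_label)
    items
  })
}

#' Mine association rules between drug classes and the endpoint
#'
#' Exact enumeration of all antecedent item sets of size 1 to
#' `config$max_antecedent` drawn from the non-endpoint items. A rule
#' `antecedent -> endpoint` is retained when
#' support = P(antecedent and endpoint) >= `min_support` and
#' confidence = P(endpoint | antecedent) >= `min_confidence`.
#' Rules are ordered by decreasing support, ties broken lexicographically on
#' the antecedent labels, so output is invariant to transaction order.
#'
#' @param transactions List of character vectors (see [atc_transactions()]).
#' @param config A [screening_config()].
#' @param endpoint_label The consequent label.
#' @return Data frame with columns `antecedent` (items joined by `"+"`),
#'   `support`, `confidence`, `n_antecedent` — zero rows when nothing passes.
#' @export
mine_rules <- function(transactions, config = screening_config(),
                       endpoint_label = "significant_me") {
  empty <- data.frame(antecedent = character(0), support = numeric(0),
                      confidence = numeric(0), n_antecedent = integer(0),
                      stringsAsFactors = FALSE)
  n <- length(transactions)
  if (n == 0) return(empty)
  has_endpoint <- vapply(transactions, function(t) endpoint_label %in% t,
                         logical(1))
  items <- sort(unique(setdiff(unlist(transactions), endpoint_label)))
  if (length(items) == 0) return(empty)
  rows <- list()
  for (k in seq_len(min(config$max_antecedent, length(items)))) {
    for (idx in utils::combn(length(items), k, simplify = FALSE)) {
      ante <- items[idx]
      has_ante <- vapply(transactions, function(t) all(ante %in% t),
                         logical(1))
      n_ante <- sum(has_ante)
      if (n_ante == 0) next
      supp <- sum(has_ante & has_endpoint) / n
      conf <- sum(has_ante & has_endpoint) / n_ante
      if (supp >= config$min_support && conf >= config$min_confidence) {
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(ante, collapse = "+"),
          support = supp, confidence = conf, n_antecedent = k,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$support, out$antecedent), , drop = FALSE]
}

#' Union of drug classes appearing in retained rules
#'
#' @param rules Data frame from [mine_rules()].
#' @return Sorted character vector of class labels (set semantics).
#' @export
select_candidate_classes <- function(rules) {
  if (nrow(rules) == 0) return(character(0))
  sort(unique(unlist(strsplit(rules$antecedent, "+", fixed = TRUE))))
}
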