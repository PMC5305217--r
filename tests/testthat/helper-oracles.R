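# Independent oracles used to check the implementation on small fixtures.

# O(n^2) pair-counting concordance: every event x non-event pair, ties 1/2.
oracle_c_statistic <- function(p, y) {
  ev <- p[y == 1]
  ne <- p[y == 0]
  tot <- 0
  for (a in ev) for (b in ne) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ev) * length(ne))
}

# Yates-corrected chi-square on a 2x2 table, straight from the formula.
oracle_yates_p <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - E) - 0.5)^2 / E)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Brute-force association-rule enumeration over all antecedent subsets.
oracle_rules <- function(transactions, min_support, min_confidence,
                         max_antecedent = 2, endpoint = "significant_me") {
  n <- length(transactions)
  items <- sort(unique(setdiff(unlist(transactions), endpoint)))
  out <- list()
  for (k in seq_len(min(max_antecedent, length(items)))) {
    for (idx in utils::combn(length(items), k, simplify = FALSE)) {
      ante <- items[idx]
      with_ante <- sum(vapply(transactions,
                              function(t) all(ante %in% t), logical(1)))
      both <- sum(vapply(transactions,
                         function(t) all(c(ante, endpoint) %in% t),
                         logical(1)))
      if (with_ante == 0) next
      if (both / n >= min_support && both / with_ante >= min_confidence) {
        out[[length(out) + 1L]] <- data.frame(
          antecedent = paste(ante, collapse = "+"),
          support = both / n, confidence = both / with_ante,
          n_antecedent = k, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(antecedent = character(0), support = numeric(0),
                      confidence = numeric(0), n_antecedent = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(-res$support, res$antecedent), , drop = FALSE]
}

# Small cohort with outcomes drawn from the frozen reference coefficients.
make_test_cohort <- function(n, seed = 1L, outcome_seed = seed + 1L) {
  assign_outcomes(generate_cohort(cohort_spec(n, seed = seed)),
                  published_true_model(), seed = outcome_seed)
}

# One fully specified patient row for the frozen scorer; fields overridable.
make_patient <- function(...) {
  base <- data.frame(age = 60, n_drugs = 0,
                     treatment_initiated_before_admission = 0,
                     bpmh_available = 0, atc_N05 = 0, atc_B05 = 0,
                     surgical_admission = 0, prior_hospitalization_30d = 0,
                     admission_from_ed = 0, night_admission = 0,
                     admission_from_outside = 0)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
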