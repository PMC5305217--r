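#' @name severity-codes
#' @title Medication-error severity codes
#' @description
#' Medication errors are graded on the NCC MERP index and collapsed to four
#' codes: `"C"` (no potential harm), `"D"` (requires monitoring or
#' intervention to preclude harm), `"E+"` (potential harm, NCC MERP category
#' E and above) and `"H"` (actual harm occurred). Events of interest — the
#' clinically significant errors that define the study endpoint — are all
#' records graded D or above, i.e. `{D, E+, H}`; category C is excluded.
NULL

.severity_levels <- c("C", "D", "E+", "H")
.significant_levels <- c("D", "E+", "H")

.validate_records <- function(records) {
  required <- c("patient_id", "severity", "day")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("medication-error records lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(records$severity), .severity_levels)
  if (length(bad) > 0) {
    stop("unknown severity code(s): ", paste(bad, collapse = ", "),
         "; expected C, D, E+ or H", call. = FALSE)
  }
  if (nrow(records) > 0 && any(is.na(records$day) | records$day < 1)) {
    stop("hospitalization day must be a positive integer", call. = FALSE)
  }
  invisible(TRUE)
}

#' Tabulate medication-error severities
#'
#' Counts records per severity code and derives the number of events of
#' interest (severity D or above). Percentages are computed over all reported
#' errors, including harmless category-C records.
#'
#' @param records Data frame with columns `patient_id`, `severity`, `day`
#'   (see [severity-codes]).
#' @return A list of class `severity_tabulation`: `counts` (named integer
#'   vector over `C`, `D`, `E+`, `H`), `total`, `events_of_interest` and
#'   `percentages`.
#' @examples
#' recs <- data.frame(patient_id = 1:4, severity = c("C", "D", "E+", "H"),
#'                    day = 1L)
#' tabulate_severity(recs)$events_of_interest
#' @export
tabulate_severity <- function(records) {
  .validate_records(records)
  counts <- vapply(.severity_levels,
                   function(s) sum(records$severity == s), integer(1))
  total <- sum(counts)
  structure(list(counts = counts,
                 total = total,
                 events_of_interest = sum(counts[.significant_levels]),
                 percentages = if (total > 0) 100 * counts / total
                               else counts * 0),
            class = "severity_tabulation")
}

#' @export
print.severity_tabulation <- function(x, ...) {
  cat("Medication-error severity tabulation\n")
  for (s in names(x$counts)) {
    cat(sprintf("  %-3s %5d (%.1f%%)\n", s, x$counts[[s]], x$percentages[[s]]))
  }
  cat(sprintf("  total %d; events of interest (D and above): %d\n",
              x$total, x$events_of_interest))
  invisible(x)
}

#' Derive the binary study endpoint from error-level records
#'
#' Sets `outcome = 1` for every patient with at least one clinically
#' significant medication error (severity D or above) at any time during the
#' stay, `0` otherwise.
#'
#' @param cohort Cohort data frame with a `patient_id` column.
#' @param records Medication-error records (see [severity-codes]).
#' @param strict If `TRUE`, records whose `patient_id` is absent from the
#'   cohort raise an error; otherwise they are dropped with a warning.
#' @return The cohort with a binary `outcome` column (replaced if present).
#' @export
derive_endpoint <- function(cohort, records, strict = FALSE) {
  .validate_records(records)
  orphan <- !(records$patient_id %in% cohort$patient_id)
  if (any(orphan)) {
    msg <- sprintf("%d record(s) reference patients absent from the cohort",
                   sum(orphan))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    records <- records[!orphan, , drop = FALSE]
  }
  sig <- records$severity %in% .significant_levels
  positive <- unique(records$patient_id[sig])
  cohort$outcome <- as.integer(cohort$patient_id %in% positive)
  cohort
}

#' Histogram of significant errors by hospitalization day
#'
#' Counts clinically significant records (severity D or above) per
#' hospitalization day. On realistic fixtures the mode falls on day 1, where
#' most admission-order discrepancies surface.
#'
#' @param records Medication-error records (see [severity-codes]).
#' @return Named integer vector, names the day, values the counts; empty for
#'   no significant records.
#' @export
day_histogram <- function(records) {
  .validate_records(records)
  sig <- records[records$severity %in% .significant_levels, , drop = FALSE]
  if (nrow(sig) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(sig$day)
  stats::setNames(as.integer(tab), names(tab))
}
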