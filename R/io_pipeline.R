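#' Load and validate a cohort CSV
#'
#' Reads an RFC-4180 headered CSV of one row per admission, checks mandatory
#' columns (case-insensitive header match) and row-level invariants: age at
#' least 18, non-negative drug count, binary flags. Rows with missing
#' predictor values are excluded complete-case with a logged count; no
#' imputation is performed.
#'
#' @param path Path to the CSV file.
#' @param required Mandatory columns; defaults to `patient_id`, `age`,
#'   `n_drugs`.
#' @param strict If `TRUE`, any invalid row aborts the load with its row
#'   number; otherwise invalid rows are dropped with a warning.
#' @return Validated data frame.
#' @export
load_cohort <- function(path, required = c("patient_id", "age", "n_drugs"),
                        strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cohort <- utils::read.csv(path)
  names(cohort) <- tolower(names(cohort))
  missing_cols <- setdiff(tolower(required), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_age <- which(!is.na(cohort$age) & cohort$age < 18)
  bad_drugs <- which(!is.na(cohort$n_drugs) & cohort$n_drugs < 0)
  incomplete <- which(!stats::complete.cases(
    cohort[, tolower(required), drop = FALSE]))
  bad <- sort(unique(c(bad_age, bad_drugs, incomplete)))
  if (length(bad) > 0) {
    msg <- sprintf("%d invalid row(s) (first at line %d): %s",
                   length(bad), bad[1] + 1L,
                   paste(c(if (length(bad_age)) "age < 18",
                           if (length(bad_drugs)) "negative drug count",
                           if (length(incomplete)) "missing values"),
                         collapse = "; "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; rows excluded (complete-case)", call. = FALSE)
    cohort <- cohort[-bad, , drop = FALSE]
  }
  cohort
}

#' Load a medication-error records CSV
#'
#' Columns `patient_id`, `severity` (codes `C`, `D`, `E+`, `H`) and `day`.
#'
#' @param path Path to the CSV file.
#' @return Validated records data frame.
#' @export
load_me_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  records <- utils::read.csv(path)
  names(records) <- tolower(names(records))
  .validate_records(records)
  records
}

#' End-to-end pipeline configuration
#'
#' Assembles the configuration of [run_pipeline()]; can be read from a YAML
#' file with [pipeline_config_from_yaml()].
#'
#' @param n_patients Size of the generated development cohort.
#' @param seed Master seed for the whole run.
#' @param screening A [screening_config()].
#' @param retention_alpha Backward-elimination threshold.
#' @param n_bootstrap Bootstrap replicates for internal validation.
#' @param sim A [sim_config()].
#' @param cohort_csv Optional path to an existing cohort CSV; when `NULL` a
#'   synthetic cohort is generated from the default [cohort_spec()] and
#'   outcomes are drawn from the published coefficients.
#' @param out_dir Output directory for artifacts.
#' @param verbose Log stage boundaries with record counts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 1408L, seed = 1L,
                            screening = screening_config(),
                            retention_alpha = 0.30,
                            n_bootstrap = 500L,
                            sim = sim_config(master_seed = seed),
                            cohort_csv = NULL,
                            out_dir = tempfile("mederrisk_run_"),
                            verbose = TRUE) {
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 screening = screening,
                 retention_alpha = retention_alpha,
                 n_bootstrap = as.integer(n_bootstrap),
                 sim = sim, cohort_csv = cohort_csv,
                 out_dir = out_dir, verbose = verbose),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose top-level keys are the
#'   `pipeline_config()` arguments (`screening` and `sim` as nested maps).
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  scr <- do.call(screening_config, y$screening %||% list())
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$coverages)) {
    sim_args$coverages <- as.numeric(sim_args$coverages)
  }
  sim <- do.call(sim_config, sim_args)
  args <- y[setdiff(names(y), c("screening", "sim"))]
  do.call(pipeline_config, c(args, list(screening = scr, sim = sim)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[mederrisk] ", fmt), ...))
  invisible(NULL)
}

#' Run the full development-and-evaluation pipeline
#'
#' Orchestrates every stage on one cohort: generation (or loading), predictor
#' screening (univariate tests plus association-rule mining over the ATC
#' indicators), model fitting (fractional-polynomial age terms, permissive
#' backward elimination), bootstrap internal validation with uniform
#' shrinkage, and the simulated-trial suite. All artifacts are written under
#' `config$out_dir` (screening report CSV, model JSON, validation JSON,
#' simulation summary CSV) with the master seed and a config hash embedded
#' for provenance.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with `cohort`, `screening`, `rules`, `model`
#'   (shrunken), `validation`, `sim_summary` and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- config$verbose

  if (is.null(config$cohort_csv)) {
    spec <- cohort_spec(config$n_patients, seed = config$seed)
    cohort <- assign_outcomes(generate_cohort(spec), published_true_model(),
                              seed = config$seed + 1L)
    cohort$true_p <- NULL
  } else {
    cohort <- load_cohort(config$cohort_csv)
  }
  .log_stage(v, "cohort: %d patients, %d events (%.1f%%)", nrow(cohort),
             sum(cohort$outcome), 100 * mean(cohort$outcome))

  screening <- screen_predictors(cohort, config = config$screening)
  rules <- mine_rules(atc_transactions(cohort), config = config$screening)
  classes <- select_candidate_classes(rules)
  eligible <- screening$variable[screening$eligible %in% TRUE]
  candidates <- union(setdiff(eligible, grep("^atc_", eligible, value = TRUE)),
                      classes)
  candidates <- setdiff(candidates, "age")
  .log_stage(v, "screening: %d eligible variables, %d rule-selected classes",
             length(eligible), length(classes))

  model_fn <- function(dat) fit_model_pipeline(
    dat, predictors = intersect(candidates, names(dat)), age_var = "age",
    retention_alpha = config$retention_alpha)
  model <- model_fn(cohort)
  .log_stage(v, "model: %d terms retained, deviance %.1f",
             length(model$coefficients), model$deviance)

  validation <- bootstrap_validate(model_fn, cohort, b = config$n_bootstrap,
                                   seed = config$seed + 2L)
  shrunk <- apply_shrinkage(model, min(1, validation$shrinkage_factor),
                            cohort)
  .log_stage(v, "validation: apparent c %.3f, corrected c %.3f, shrinkage %.3f",
             validation$apparent_c, validation$corrected_c,
             validation$shrinkage_factor)

  sim_summary <- run_suite(cohort, config$sim)
  .log_stage(v, "simulation: %d coverages x %d replicates",
             length(config$sim$coverages), config$sim$replicates)

  provenance <- list(seed = config$seed,
                     config_digest = .config_digest(config))
  utils::write.csv(screening,
                   file.path(config$out_dir, "screening_report.csv"),
                   row.names = FALSE)
  utils::write.csv(rules, file.path(config$out_dir, "association_rules.csv"),
                   row.names = FALSE)
  model_to_json(shrunk, file.path(config$out_dir, "model.json"))
  jsonlite::write_json(c(unclass(validation), provenance),
                       file.path(config$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(cbind(as.data.frame(sim_summary),
                         seed = config$seed,
                         config_digest = provenance$config_digest),
                   file.path(config$out_dir, "sim_summary.csv"),
                   row.names = FALSE)
  invisible(list(cohort = cohort, screening = screening, rules = rules,
                 model = shrunk, validation = validation,
                 sim_summary = sim_summary, out_dir = config$out_dir))
}

# Stable short digest of a configuration (provenance stamp in artifacts);
# run-location fields are excluded so identical analyses stamp identically.
.config_digest <- function(config) {
  config <- unclass(config)
  config$out_dir <- NULL
  config$verbose <- NULL
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)))
}
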