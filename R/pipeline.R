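# End-to-end orchestration: generate/ingest -> map -> outcomes -> split ->
# fit -> evaluate -> report, with seeded determinism and a run manifest.

fmt_pct <- function(count, n) round(100 * count / n, 1)

#' Cohort summary table
#'
#' Baseline characteristics in the usual case-mix reporting layout: counts
#' with percents (one decimal) and medians with interquartile ranges.
#'
#' @param cohort an `elix_cohort`.
#' @param outcomes outcome data frame from [build_outcomes()].
#' @return a list with `n`, `male_n`/`male_pct`, `age_median`/`age_iqr`,
#'   `los_median`/`los_iqr`, `emergency_n`/`emergency_pct`, and per-outcome
#'   counts and percents.
#' @export
summarize_cohort <- function(cohort, outcomes = build_outcomes(cohort)) {
  h <- cohort$hospitalizations
  n <- nrow(h)
  if (n == 0) stop("empty cohort")
  qs <- function(x) unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  age_q <- qs(h$age_years)
  los_q <- qs(outcomes$los_days)
  list(n = n,
       male_n = sum(h$sex == "male"),
       male_pct = fmt_pct(sum(h$sex == "male"), n),
       age_median = age_q[2], age_iqr = age_q[c(1, 3)],
       los_median = los_q[2], los_iqr = los_q[c(1, 3)],
       emergency_n = sum(h$admission_source == "emergency"),
       emergency_pct = fmt_pct(sum(h$admission_source == "emergency"), n),
       mortality_n = sum(outcomes$died),
       mortality_pct = fmt_pct(sum(outcomes$died), n),
       escalation_n = sum(outcomes$escalation),
       escalation_pct = fmt_pct(sum(outcomes$escalation), n),
       readmission_n = sum(outcomes$readmit_30d),
       readmission_pct = fmt_pct(sum(outcomes$readmit_30d), n))
}

model_to_list <- function(model) {
  out <- list(outcome = model$outcome, family = model$family,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              standard_errors = as.list(model$standard_errors),
              ci_low = as.list(model$ci_95[, "low"]),
              ci_high = as.list(model$ci_95[, "high"]),
              p_values = as.list(model$p_values),
              n_obs = model$n_obs, converged = model$converged)
  if (model$family == "linear") {
    out$r_squared <- model$r_squared
    out$adj_r_squared <- model$adj_r_squared
  }
  out
}

evaluation_to_list <- function(ev) {
  if (ev$family == "logistic") {
    list(outcome = ev$outcome, family = ev$family,
         c_derivation = ev$c_derivation, c_validation = ev$c_validation,
         hl_derivation = c(list(table = ev$hl_derivation$groups),
                           ev$hl_derivation[c("statistic", "df", "p_value")]),
         hl_validation = c(list(table = ev$hl_validation$groups),
                           ev$hl_validation[c("statistic", "df", "p_value")]))
  } else {
    list(outcome = ev$outcome, family = ev$family,
         r2_derivation = ev$r2_derivation,
         adj_r2_derivation = ev$adj_r2_derivation,
         r2_validation = ev$r2_validation)
  }
}

#' Run the full risk-adjustment pipeline
#'
#' Takes a cohort (read from the interchange files or generated
#' synthetically), assigns comorbidity flags with the hierarchy (and
#' optional DRG screen), builds the four outcomes, splits 70/30 into
#' derivation and validation sets, fits one model per requested outcome on
#' the derivation set, forces the coefficients onto the validation set, and
#' writes prevalence, coefficient, model and evaluation artifacts plus a
#' manifest with content hashes.
#'
#' @param input either an `elix_cohort`, or a named list of file paths
#'   (`hospitalizations`, `ward_stays`, `treatment_events`), or `NULL` to
#'   generate from `generator`.
#' @param generator a [generator_config()] (used when `input` is NULL).
#' @param out_dir output directory for artifacts, or `NULL` to skip writing.
#' @param split_fraction derivation fraction (default 0.7).
#' @param seed split seed (required).
#' @param outcomes_subset subset of
#'   `c("mortality", "escalation", "readmission", "log_los")`.
#' @param exclusions,min_count condition selection, see [select_conditions()].
#' @param drg_screen apply the DRG screen (default off: the screen needs DRG
#'   codes, which many systems do not assign).
#' @param escalation an [escalation_config()].
#' @param readmission_window days (default 30).
#' @param definitions compiled [elix_definitions()].
#' @return list of class `elix_run` with `prevalence`, `conditions`,
#'   `split`, `models`, `evaluations`, `summary`, and `artifacts` (paths).
#' @export
run_pipeline <- function(input = NULL, generator = NULL, out_dir = NULL,
                         split_fraction = 0.7, seed,
                         outcomes_subset = c("mortality", "escalation",
                                             "readmission", "log_los"),
                         exclusions = "blood_loss_anemia", min_count = 0,
                         drg_screen = FALSE,
                         escalation = escalation_config(),
                         readmission_window = 30,
                         definitions = elix_definitions()) {
  outcomes_subset <- match.arg(outcomes_subset, several.ok = TRUE)
  if (is.null(input) && is.null(generator))
    stop("supply exactly one of `input` or `generator`")
  if (!is.null(input) && !is.null(generator))
    stop("supply exactly one of `input` or `generator`")

  if (!is.null(input)) {
    cohort <- if (inherits(input, "elix_cohort")) input
    else read_hospitalizations(input$hospitalizations, input$ward_stays,
                               input$treatment_events)
  } else {
    cohort <- generate_records(generator)$cohort
  }
  h <- cohort$hospitalizations
  n <- nrow(h)
  message("pipeline: ", n, " hospitalizations in")

  flags <- flag_matrix(h$diagnosis_codes, definitions)
  flags <- apply_hierarchy(flags)
  if (drg_screen) flags <- apply_drg_screen(flags, h$drg, definitions)
  prevalence <- prevalence_table(flags, definitions)
  conditions <- select_conditions(prevalence, exclusions, min_count)
  message("pipeline: ", length(conditions), " conditions retained")

  outcome_df <- build_outcomes(cohort, escalation, readmission_window)
  split <- split_sample(h$hospitalization_id, split_fraction, seed)
  X <- design_matrix(flags, conditions, h$hospitalization_id)
  der <- rownames(X) %in% split$derivation_ids
  message("pipeline: split ", sum(der), "/", sum(!der))

  # a condition never (or always) observed in the derivation set cannot be
  # estimated; drop it from the design rather than fail the whole run
  der_counts <- colSums(X[der, , drop = FALSE])
  const <- conditions[der_counts == 0 | der_counts == sum(der)]
  if (length(const)) {
    message("pipeline: dropping condition(s) unobserved in the derivation set: ",
            paste(const, collapse = ", "))
    conditions <- setdiff(conditions, const)
    X <- X[, conditions, drop = FALSE]
  }

  spec <- list(
    mortality = list(y = outcome_df$died, family = "logistic"),
    escalation = list(y = outcome_df$escalation, family = "logistic"),
    readmission = list(y = outcome_df$readmit_30d, family = "logistic"),
    log_los = list(y = outcome_df$log_los, family = "linear"))
  models <- list()
  evaluations <- list()
  for (name in outcomes_subset) {
    s <- spec[[name]]
    fit_fn <- if (s$family == "logistic") fit_logistic else fit_linear
    models[[name]] <- fit_fn(X[der, , drop = FALSE], s$y[der], outcome = name)
    evaluations[[name]] <- evaluate_model(
      models[[name]], X[der, , drop = FALSE], s$y[der],
      X[!der, , drop = FALSE], s$y[!der])
  }

  result <- structure(
    list(prevalence = prevalence, conditions = conditions, split = split,
         models = models, evaluations = evaluations,
         summary = summarize_cohort(cohort, outcome_df),
         seed = as.integer(seed), artifacts = character(0)),
    class = "elix_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(prevalence = file.path(out_dir, "prevalence.csv"),
               models = file.path(out_dir, "models.json"),
               evaluation = file.path(out_dir, "evaluation.json"))
    utils::write.csv(prevalence, paths["prevalence"], row.names = FALSE)
    jsonlite::write_json(
      list(seed = result$seed, split_fraction = split_fraction,
           derivation_n = length(split$derivation_ids),
           validation_n = length(split$validation_ids),
           conditions = conditions,
           models = lapply(models, model_to_list)),
      paths["models"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(lapply(evaluations, evaluation_to_list),
                         paths["evaluation"], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    for (name in names(models)) {
      p <- file.path(out_dir, paste0("coefficients_", name, ".csv"))
      utils::write.csv(coefficient_table(models[[name]]), p, row.names = FALSE)
      paths[paste0("coefficients_", name)] <- p
    }
    manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(seed = result$seed, n = n,
           files = as.list(tools::md5sum(unname(paths)))),
      manifest, auto_unbox = TRUE, pretty = TRUE)
    result$artifacts <- c(paths, manifest = manifest)
  }
  result
}

#' @export
print.elix_run <- function(x, ...) {
  cat("<elix_run> n=", x$summary$n, ", ", length(x$conditions),
      " conditions, outcomes: ", paste(names(x$models), collapse = ", "),
      "\n", sep = "")
  for (name in names(x$evaluations)) {
    ev <- x$evaluations[[name]]
    if (ev$family == "logistic")
      cat(sprintf("  %-11s c = %.3f (derivation) / %.3f (validation)\n",
                  name, ev$c_derivation, ev$c_validation))
    else
      cat(sprintf("  %-11s R2 = %.3f (derivation) / %.3f (validation)\n",
                  name, ev$r2_derivation, ev$r2_validation))
  }
  invisible(x)
}
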