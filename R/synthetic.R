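# Seeded synthetic-hospitalization generator. Emits raw records (diagnosis
# codes, ward stays, treatment events, readmission chains) whose statistical
# structure matches the analysis assumptions, together with ground-truth
# comorbidity profiles and outcome labels, so every upstream stage can be
# tested round-trip without patient data.

#' Generator configuration
#'
#' Bundles every tunable of the synthetic generator. Defaults emulate a
#' large internal-medicine service: condition prevalences from
#' [default_prevalences()], ground-truth effect sizes equal to the natural
#' logs of the reference odds-ratio tables (log-day betas for length of
#' stay), marginal outcome rates 6.9% mortality / 13% escalation / 15%
#' 30-day readmission, and median length of stay near 4.1 days.
#'
#' `los_noise_sd`, when left `NULL`, is set by the R-squared calibration
#' rule: `sd = sqrt(Var(X beta) (1 - r2) / r2)` with `Var(X beta)` computed
#' analytically from the prevalences (independent flags, with the two
#' mutually exclusive severity pairs accounted for), so the linear model's
#' expected R-squared equals `los_target_r2` (default 0.102). Likewise a
#' `NULL` `los_baseline` is chosen so the expected log length of stay equals
#' `log(4.1)`.
#'
#' @param n number of hospitalizations (at least 100).
#' @param seed integer seed; all generator randomness flows from it.
#' @param prevalences named per-condition probabilities.
#' @param or_mortality,or_escalation,or_readmission named ground-truth odds
#'   ratios for the three binary outcomes (one per analysis condition).
#' @param beta_log_los named ground-truth log-day effects.
#' @param target_rates named marginal rates for mortality, escalation,
#'   readmission.
#' @param los_baseline baseline log length of stay (`NULL` = calibrate).
#' @param los_noise_sd residual SD of log length of stay (`NULL` = calibrate).
#' @param los_target_r2 expected R-squared used by the noise calibration.
#' @param noise_code_mean Poisson mean of non-informative extra codes.
#' @param readmission_window days (boundary inclusive).
#' @param escalation an [escalation_config()]; realized events respect it.
#' @param definitions compiled [elix_definitions()].
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n, seed,
                             prevalences = default_prevalences(),
                             or_mortality = default_or_mortality,
                             or_escalation = default_or_escalation,
                             or_readmission = default_or_readmission,
                             beta_log_los = default_beta_log_los,
                             target_rates = default_outcome_rates,
                             los_baseline = NULL,
                             los_noise_sd = NULL,
                             los_target_r2 = 0.102,
                             noise_code_mean = 2,
                             readmission_window = 30,
                             escalation = escalation_config(),
                             definitions = elix_definitions()) {
  stopifnot(n >= 100, all(prevalences > 0 & prevalences < 1),
            all(target_rates > 0 & target_rates < 1),
            los_target_r2 > 0, los_target_r2 < 1)
  conditions <- names(definitions)
  stopifnot(all(names(prevalences) %in% conditions),
            setequal(names(or_mortality), names(beta_log_los)))

  var_eta <- function(beta) linear_predictor_variance(beta, prevalences)
  if (is.null(los_noise_sd)) {
    v <- var_eta(beta_log_los)
    los_noise_sd <- sqrt(v * (1 - los_target_r2) / los_target_r2)
  }
  if (is.null(los_baseline)) {
    los_baseline <- log(4.1) -
      sum(beta_log_los * prevalences[names(beta_log_los)])
  }
  stopifnot(los_noise_sd > 0)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 prevalences = prevalences,
                 outcome_models = list(
                   mortality = list(coefficients = log(or_mortality),
                                    target_rate = target_rates[["mortality"]]),
                   escalation = list(coefficients = log(or_escalation),
                                     target_rate = target_rates[["escalation"]]),
                   readmission = list(coefficients = log(or_readmission),
                                      target_rate = target_rates[["readmission"]])),
                 los_model = list(betas = beta_log_los,
                                  baseline = los_baseline,
                                  noise_sd = los_noise_sd,
                                  target_r2 = los_target_r2),
                 noise_code_mean = noise_code_mean,
                 readmission_window = as.integer(readmission_window),
                 escalation = escalation,
                 definitions = definitions),
            class = "generator_config")
}

# Var(X beta) for independent Bernoulli flags, minus the covariance of the
# two mutually exclusive severity pairs (P(both) = 0, so cov = -p1 p2).
linear_predictor_variance <- function(beta, prevalences) {
  p <- prevalences[names(beta)]
  v <- sum(beta^2 * p * (1 - p))
  pair_cov <- function(a, b) {
    if (all(c(a, b) %in% names(beta)))
      -2 * beta[[a]] * beta[[b]] * p[[a]] * p[[b]]
    else 0
  }
  v + pair_cov("diabetes_uncomplicated", "diabetes_complicated") +
    pair_cov("solid_tumor", "metastatic_cancer")
}

# unseeded core: hierarchy-consistent flag draws
draw_profiles <- function(n, prevalences, conditions = names(prevalences)) {
  flags <- matrix(FALSE, n, length(conditions),
                  dimnames = list(NULL, conditions))
  paired <- c("diabetes_uncomplicated", "diabetes_complicated",
              "solid_tumor", "metastatic_cancer")
  for (key in setdiff(conditions, paired)) {
    flags[, key] <- stats::runif(n) < prevalences[[key]]
  }
  split_pair <- function(mild, severe) {
    if (!all(c(mild, severe) %in% conditions)) {
      for (key in intersect(c(mild, severe), conditions))
        flags[, key] <<- stats::runif(n) < prevalences[[key]]
      return(invisible(NULL))
    }
    u <- stats::runif(n)
    flags[, severe] <<- u < prevalences[[severe]]
    flags[, mild] <<- !flags[, severe] &
      u < prevalences[[severe]] + prevalences[[mild]]
  }
  split_pair("diabetes_uncomplicated", "diabetes_complicated")
  split_pair("solid_tumor", "metastatic_cancer")
  flags
}

#' Draw ground-truth comorbidity profiles
#'
#' Condition flags are drawn independently at the configured prevalences,
#' except that each severity pair (uncomplicated/complicated diabetes, solid
#' tumor/metastatic cancer) is drawn as a single multinomial split so a
#' profile is hierarchy-consistent by construction: both members are never
#' simultaneously true, and each member keeps its marginal prevalence.
#'
#' @param cfg a [generator_config()].
#' @return logical matrix, `cfg$n` rows by 30 condition columns.
#' @export
generate_profiles <- function(cfg) {
  with_seed(cfg$seed, function() draw_profiles(cfg$n, cfg$prevalences))
}

#' Calibrate a logistic intercept to a marginal event rate
#'
#' Root-finds the intercept `a` such that the population-averaged event
#' probability `E[plogis(a + X beta)]` equals `target_rate`. The expectation
#' is taken over a Monte-Carlo sample of profiles at the given prevalences
#' (or over a supplied linear-predictor sample `eta`, in which case the
#' calibration is exact for that sample).
#'
#' @param coefficients named log-odds vector.
#' @param prevalences named condition prevalences (used when `eta` is NULL).
#' @param target_rate desired marginal rate in (0, 1).
#' @param eta optional numeric sample of `X beta` values.
#' @param mc_n Monte-Carlo sample size.
#' @param mc_seed seed for the Monte-Carlo draw.
#' @return the intercept (a scalar).
#' @examples
#' calibrate_intercept(c(x = 0), c(x = 0.5), 0.069)  # = qlogis(0.069)
#' @export
calibrate_intercept <- function(coefficients, prevalences, target_rate,
                                eta = NULL, mc_n = 200000, mc_seed = 1) {
  stopifnot(target_rate > 0, target_rate < 1)
  if (is.null(eta)) {
    X <- with_seed(mc_seed, function()
      draw_profiles(mc_n, prevalences[names(prevalences) %in%
                                        names(coefficients)]))
    eta <- drop(X[, names(coefficients), drop = FALSE] %*% coefficients)
  }
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - target_rate,
                 interval = c(-40, 40), tol = 1e-10)$root
}

# unseeded core: outcome labels given a flag matrix
draw_outcome_labels <- function(flags, cfg) {
  n <- nrow(flags)
  labels <- list()
  intercepts <- numeric(0)
  for (name in names(cfg$outcome_models)) {
    m <- cfg$outcome_models[[name]]
    X <- flags[, names(m$coefficients), drop = FALSE] * 1
    eta <- drop(X %*% m$coefficients)
    a <- calibrate_intercept(m$coefficients, cfg$prevalences, m$target_rate,
                             eta = eta)
    labels[[name]] <- stats::runif(n) < stats::plogis(a + eta)
    intercepts[[name]] <- a
  }
  lm_ <- cfg$los_model
  Xl <- flags[, names(lm_$betas), drop = FALSE] * 1
  log_los <- lm_$baseline + drop(Xl %*% lm_$betas) +
    stats::rnorm(n, 0, lm_$noise_sd)
  data.frame(died = labels$mortality, escalation = labels$escalation,
             readmit_30d = labels$readmission, log_los = log_los,
             los_days = exp(log_los)) |>
    structure(intercepts = intercepts)
}

#' Simulate outcome labels for a flag matrix
#'
#' Draws the three binary outcomes from their ground-truth logistic models
#' (intercepts calibrated on the realized linear predictors, so the sample
#' mean probability hits the target rate exactly) and log length of stay
#' from the linear model with Gaussian noise. Labels only - no raw events
#' are realized; use [generate_records()] for full records.
#'
#' @param flags logical flag matrix (e.g. from [generate_profiles()]).
#' @param cfg a [generator_config()].
#' @param seed optional seed; defaults to `cfg$seed + 1` so that profile and
#'   label draws are independent streams.
#' @return data frame with `died`, `escalation`, `readmit_30d`, `log_los`,
#'   `los_days`; calibrated intercepts in attribute `intercepts`.
#' @export
simulate_outcome_labels <- function(flags, cfg, seed = cfg$seed + 1) {
  with_seed(seed, function() draw_outcome_labels(flags, cfg))
}

#' Code pools for realizing profiles as diagnosis codes
#'
#' Expands every condition's patterns into explicit code strings and keeps
#' only codes that map back to exactly that condition, so sampled codes can
#' never activate a foreign flag. Also verifies the configured noise codes
#' match no condition.
#'
#' @param definitions compiled definitions.
#' @param noise_codes candidate non-informative codes.
#' @return list with `condition` (list of code vectors per key) and `noise`.
#' @export
build_code_pools <- function(definitions = elix_definitions(),
                             noise_codes = default_noise_codes) {
  keys <- names(definitions)
  raw_pools <- lapply(definitions, function(d)
    unique(unlist(lapply(d$patterns, expand_pattern))))
  all_codes <- unique(c(unlist(raw_pools), noise_codes))
  norm <- normalize_icd9(all_codes)
  hits <- matrix(FALSE, length(all_codes), length(keys),
                 dimnames = list(all_codes, keys))
  for (key in keys) {
    for (pat in definitions[[key]]$patterns)
      hits[, key] <- hits[, key] | code_matches(pat, norm)
  }
  n_hits <- rowSums(hits)
  pools <- lapply(keys, function(key)
    raw_pools[[key]][hits[raw_pools[[key]], key] &
                       n_hits[raw_pools[[key]]] == 1])
  names(pools) <- keys
  empty <- keys[lengths(pools) == 0]
  if (length(empty))
    stop("no unambiguous codes available for: ", paste(empty, collapse = ", "))
  bad_noise <- noise_codes[n_hits[noise_codes] > 0]
  if (length(bad_noise))
    stop("noise code(s) map to a condition: ", paste(bad_noise, collapse = ", "))
  list(condition = pools, noise = noise_codes)
}

#' Realize a comorbidity profile as a diagnosis-code list
#'
#' Emits one uniformly sampled code from the pool of each flagged condition,
#' plus a Poisson-distributed number of non-informative noise codes. Emitted
#' codes never activate a condition whose flag is false, so mapping the codes
#' back through the comorbidity mapper reproduces the profile exactly (after
#' hierarchy - generated profiles are hierarchy-consistent already).
#'
#' @param profile named logical vector of condition flags.
#' @param pools code pools from [build_code_pools()].
#' @param noise_code_mean Poisson mean of extra noise codes.
#' @return character vector of ICD-9-CM code strings.
#' @export
profile_to_codes <- function(profile, pools, noise_code_mean = 2) {
  onsets <- names(profile)[profile]
  codes <- vapply(onsets, function(key) {
    pool <- pools$condition[[key]]
    pool[sample.int(length(pool), 1)]
  }, character(1))
  n_noise <- stats::rpois(1, noise_code_mean)
  if (n_noise > 0)
    codes <- c(codes, sample(pools$noise, min(n_noise, length(pools$noise))))
  unname(codes)
}

# sample a whole-second timestamp inside [t0, t1] whose local (UTC) hour
# falls in one of the [lo, hi) windows; NA if the stay never touches one
sample_time_in_hours <- function(t0, t1, windows) {
  days <- seq(floor(t0 / 86400), floor(t1 / 86400))
  starts <- ends <- numeric(0)
  for (w in windows) {
    ws <- days * 86400 + w[1] * 3600
    we <- days * 86400 + w[2] * 3600
    s <- pmax(ws, t0)
    e <- pmin(we, t1)
    keep <- e > s
    starts <- c(starts, s[keep])
    ends <- c(ends, e[keep])
  }
  if (!length(starts)) return(NA_real_)
  len <- ends - starts
  u <- stats::runif(1, 0, sum(len))
  i <- findInterval(u, cumsum(c(0, len)), rightmost.closed = TRUE)
  # clamp to end - 1s: the window is half-open, so its end hour must not occur
  min(floor(starts[i] + (u - cumsum(c(0, len))[i])), ends[i] - 1)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Emits raw hospitalization records - demographics, admission timestamps
#' over a four-year window, diagnosis codes realized from the true profiles,
#' ward stays and treatment events realizing the escalation label, and
#' per-patient readmission chains realizing the readmission label - together
#' with the ground-truth profiles and outcome labels. Ages are drawn from a
#' left-skewed distribution with median about 74 (IQR roughly 61-84).
#'
#' Escalated hospitalizations receive one qualifying mechanism chosen at
#' random among an ICU stay, an IMCU stay (when the escalation configuration
#' counts IMCU), mechanical ventilation, daytime BiPAP, or a listed
#' vasopressor; non-escalated ones receive no qualifying event but may carry
#' decoys (night-time BiPAP, an unlisted-drug infusion) that must not flip
#' the label. Readmitted hospitalizations are followed by a same-patient
#' admission 1-30 days after discharge; non-readmitted ones either end the
#' patient's chain or are followed after more than the window.
#'
#' @param cfg a [generator_config()].
#' @return list with `cohort` (an `elix_cohort`), `ground_truth` (data frame
#'   of flags and outcome labels per hospitalization) and `config`.
#' @export
generate_records <- function(cfg) {
  with_seed(cfg$seed, function() generate_records_impl(cfg))
}

generate_records_impl <- function(cfg) {
  n <- cfg$n
  flags <- draw_profiles(n, cfg$prevalences)
  out <- draw_outcome_labels(flags, cfg)
  pools <- build_code_pools(cfg$definitions)

  ids <- sprintf("H%07d", seq_len(n))
  age <- pmin(104, pmax(18, 105 - stats::rlnorm(n, log(31), 0.54)))
  sex <- ifelse(stats::runif(n) < 0.53, "male", "female")
  src <- sample(admission_sources, n, replace = TRUE,
                prob = c(0.86, 0.07, 0.07))

  # readmission chains: walk records in random order; a TRUE label links the
  # next record to the same patient within the window, FALSE ends the chain
  # (or, as a decoy, continues it beyond the window)
  ord <- sample.int(n)
  if (out$readmit_30d[ord[n]]) {
    swap <- which(!out$readmit_30d[ord])
    if (!length(swap)) stop("cannot realize readmissions: all labels TRUE")
    j <- swap[length(swap)]
    ord[c(j, n)] <- ord[c(n, j)]
  }
  window_start <- as.numeric(as.POSIXct("2016-01-01", tz = "UTC"))
  window_days <- 1460L  # four-year admission window
  admit <- discharge <- numeric(n)
  patient <- character(n)
  los_sec <- pmax(600, round(out$los_days * 86400))
  n_patients <- 0L
  pending_date <- NA_real_  # next admit day number, when a chain continues
  for (i in seq_len(n)) {
    idx <- ord[i]
    if (is.na(pending_date)) {
      n_patients <- n_patients + 1L
      day <- floor(window_start / 86400) + sample.int(window_days, 1) - 1L
    } else {
      day <- pending_date
    }
    patient[idx] <- sprintf("P%07d", n_patients)
    admit[idx] <- day * 86400 + sample.int(86400, 1) - 1L
    discharge[idx] <- admit[idx] + los_sec[idx]
    dis_day <- floor(discharge[idx] / 86400)
    if (i < n && out$readmit_30d[idx]) {
      pending_date <- dis_day + sample.int(cfg$readmission_window, 1)
    } else if (i < n && stats::runif(1) < 0.25) {
      pending_date <- dis_day + cfg$readmission_window +
        sample.int(90, 1)
    } else {
      pending_date <- NA_real_
    }
  }

  # ward stays: a base internal-medicine-service stay spanning the whole
  # admission, plus an ICU/IMCU stay when that mechanism realizes escalation
  base_class <- sample(c("im_ward", "cardiology", "geriatrics", "short_stay"),
                       n, replace = TRUE, prob = c(0.70, 0.12, 0.10, 0.08))
  ws_id <- ids
  ws_class <- base_class
  ws_start <- admit
  ws_end <- discharge

  ev_id <- character(0)
  ev_kind <- character(0)
  ev_time <- numeric(0)
  ev_drug <- character(0)
  add_event <- function(id, kind, time, drug = NA_character_) {
    ev_id <<- c(ev_id, id)
    ev_kind <<- c(ev_kind, kind)
    ev_time <<- c(ev_time, time)
    ev_drug <<- c(ev_drug, drug)
  }
  esc_cfg <- cfg$escalation
  day_win <- list(c(esc_cfg$daytime_start_hour, esc_cfg$daytime_end_hour))
  night_win <- list(c(0, esc_cfg$daytime_start_hour),
                    c(esc_cfg$daytime_end_hour, 24))
  mechanisms <- c("icu", if (esc_cfg$include_imcu) "imcu",
                  "mechanical_ventilation", "bipap", "vasopressor")
  for (i in which(out$escalation)) {
    mech <- sample(mechanisms, 1)
    if (mech == "bipap") {
      t <- sample_time_in_hours(admit[i], discharge[i], day_win)
      if (is.na(t)) mech <- "icu" else add_event(ids[i], "bipap", t)
    }
    if (mech == "mechanical_ventilation") {
      add_event(ids[i], "mechanical_ventilation",
                floor(stats::runif(1, admit[i], discharge[i])))
    }
    if (mech == "vasopressor") {
      add_event(ids[i], "vasopressor",
                floor(stats::runif(1, admit[i], discharge[i])),
                sample(esc_cfg$vasopressor_names, 1))
    }
    if (mech %in% c("icu", "imcu")) {
      t1 <- floor(stats::runif(1, admit[i], admit[i] + (discharge[i] - admit[i]) / 2))
      t2 <- floor(stats::runif(1, t1, discharge[i]))
      ws_id <- c(ws_id, ids[i])
      ws_class <- c(ws_class, mech)
      ws_start <- c(ws_start, t1)
      ws_end <- c(ws_end, t2)
    }
  }
  # decoy events on non-escalated stays: night-time BiPAP and an infusion of
  # a drug that is not on the vasopressor list
  quiet <- which(!out$escalation)
  for (i in quiet[stats::runif(length(quiet)) < 0.10]) {
    t <- sample_time_in_hours(admit[i], discharge[i], night_win)
    if (!is.na(t)) add_event(ids[i], "bipap", t)
  }
  for (i in quiet[stats::runif(length(quiet)) < 0.05]) {
    add_event(ids[i], "vasopressor",
              floor(stats::runif(1, admit[i], discharge[i])), "levosimendan")
  }

  codes <- lapply(seq_len(n), function(i)
    profile_to_codes(flags[i, ], pools, cfg$noise_code_mean))

  hosp <- data.frame(
    hospitalization_id = ids, patient_id = patient,
    admit = .POSIXct(admit, tz = "UTC"),
    discharge = .POSIXct(discharge, tz = "UTC"),
    age_years = round(age, 1), sex = sex, admission_source = src,
    died_in_hospital = out$died, drg = NA_integer_,
    stringsAsFactors = FALSE)
  hosp$diagnosis_codes <- codes
  cohort <- new_cohort(
    hosp,
    data.frame(hospitalization_id = ws_id, ward_class = ws_class,
               start = .POSIXct(ws_start, tz = "UTC"),
               end = .POSIXct(ws_end, tz = "UTC"), stringsAsFactors = FALSE),
    data.frame(hospitalization_id = ev_id, kind = ev_kind,
               timestamp = .POSIXct(ev_time, tz = "UTC"),
               drug_name = ev_drug, stringsAsFactors = FALSE))

  los_days <- los_sec / 86400
  ground_truth <- data.frame(hospitalization_id = ids, flags,
                             died = out$died, escalation = out$escalation,
                             readmit_30d = out$readmit_30d,
                             los_days = los_days, log_los = log(los_days),
                             stringsAsFactors = FALSE)
  list(cohort = cohort, ground_truth = ground_truth, config = cfg)
}
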