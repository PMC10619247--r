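test_that("profiles hit configured prevalences and respect the severity pairs", {
  cfg <- generator_config(n = 10000, seed = 23)
  flags <- generate_profiles(cfg)
  p_chf <- cfg$prevalences[["congestive_heart_failure"]]
  se <- sqrt(p_chf * (1 - p_chf) / nrow(flags))
  expect_lt(abs(mean(flags[, "congestive_heart_failure"]) - p_chf), 3 * se)

  expect_false(any(flags[, "diabetes_uncomplicated"] &
                     flags[, "diabetes_complicated"]))
  expect_false(any(flags[, "solid_tumor"] & flags[, "metastatic_cancer"]))
  # the severe member keeps its own marginal prevalence under the pair split
  p_dmc <- cfg$prevalences[["diabetes_complicated"]]
  se <- sqrt(p_dmc * (1 - p_dmc) / nrow(flags))
  expect_lt(abs(mean(flags[, "diabetes_complicated"]) - p_dmc), 3 * se)

  prev0 <- replace(default_prevalences(), "obesity", 1e-12)
  flags0 <- generate_profiles(generator_config(n = 1000, seed = 2,
                                               prevalences = prev0))
  expect_equal(sum(flags0[, "obesity"]), 0L)

  expect_identical(generate_profiles(cfg), flags)  # seed determinism
})

test_that("codes realized from a profile map back to exactly that profile", {
  defs <- shared_defs()
  pools <- build_code_pools(defs)

  chf_only <- setNames(rep(FALSE, 30), names(defs))
  chf_only["congestive_heart_failure"] <- TRUE
  set.seed(1)
  codes <- profile_to_codes(chf_only, pools, noise_code_mean = 0)
  expect_length(codes, 1)
  expect_equal(apply_hierarchy(assign_flags(codes, defs)), chf_only)

  empty <- setNames(rep(FALSE, 30), names(defs))
  set.seed(1)
  expect_length(profile_to_codes(empty, pools, noise_code_mean = 0), 0)

  # round trip across many random hierarchy-consistent profiles, with noise
  cfg <- generator_config(n = 1000, seed = 31)
  flags <- generate_profiles(cfg)
  set.seed(99)
  for (i in seq_len(nrow(flags))) {
    codes <- profile_to_codes(flags[i, ], pools, noise_code_mean = 2)
    expect_equal(apply_hierarchy(assign_flags(codes, defs)), flags[i, ])
  }
})

test_that("noise codes never map to any condition", {
  defs <- shared_defs()
  m <- flag_matrix(as.list(elixadjust:::default_noise_codes), defs)
  expect_equal(sum(m), 0L)
})

test_that("intercept calibration hits target rates", {
  # no covariate effect: closed form logit(target)
  expect_equal(calibrate_intercept(c(x = 0), c(x = 0.5), 0.069),
               qlogis(0.069), tolerance = 1e-6)

  # one binary covariate: compare against the exact mixture root
  a_pkg <- calibrate_intercept(c(x = log(2)), c(x = 0.5), 0.2)
  a_exact <- uniroot(function(a)
    0.5 * plogis(a) + 0.5 * plogis(a + log(2)) - 0.2,
    c(-20, 20), tol = 1e-12)$root
  expect_equal(a_pkg, a_exact, tolerance = 0.02)

  # calibration on a realized design makes the sample mean probability exact
  cfg <- generator_config(n = 20000, seed = 55)
  flags <- generate_profiles(cfg)
  m <- cfg$outcome_models$mortality
  eta <- drop((flags[, names(m$coefficients)] * 1) %*% m$coefficients)
  a <- calibrate_intercept(m$coefficients, cfg$prevalences, m$target_rate,
                           eta = eta)
  expect_equal(mean(plogis(a + eta)), 0.069, tolerance = 1e-8)

  expect_error(calibrate_intercept(c(x = 0), c(x = 0.5), 1.5), "target_rate")
})

test_that("simulated outcome rates match the configured marginals", {
  cfg <- generator_config(n = 20000, seed = 87)
  flags <- generate_profiles(cfg)
  labs <- simulate_outcome_labels(flags, cfg)
  for (pair in list(c("died", "mortality"), c("escalation", "escalation"),
                    c("readmit_30d", "readmission"))) {
    target <- cfg$outcome_models[[pair[2]]]$target_rate
    se <- sqrt(target * (1 - target) / nrow(flags))
    expect_lt(abs(mean(labs[[pair[1]]]) - target), 3 * se)
  }
  expect_equal(labs$los_days, exp(labs$log_los))
})

test_that("full records reproduce every ground-truth label through the outcomes module", {
  sim <- generate_records(generator_config(n = 2000, seed = 12))
  out <- build_outcomes(sim$cohort, sim$config$escalation,
                        sim$config$readmission_window)
  gt <- sim$ground_truth[match(out$hospitalization_id,
                               sim$ground_truth$hospitalization_id), ]
  expect_equal(out$died, gt$died)
  expect_equal(out$escalation, gt$escalation)       # decoys never flip labels
  expect_equal(out$readmit_30d, gt$readmit_30d)
  expect_equal(out$los_days, gt$los_days, tolerance = 1e-9)
  expect_equal(out$log_los, gt$log_los, tolerance = 1e-9)

  # mapped flags reproduce the true profiles
  flags <- apply_hierarchy(flag_matrix(sim$cohort$hospitalizations$diagnosis_codes,
                                       sim$config$definitions))
  truth <- as.matrix(sim$ground_truth[, colnames(flags)])
  dimnames(truth) <- dimnames(flags)
  expect_equal(flags, truth)
})

test_that("generation is byte-deterministic in the seed and emulates the cohort shape", {
  a <- generate_records(generator_config(n = 500, seed = 41))
  b <- generate_records(generator_config(n = 500, seed = 41))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$ground_truth, b$ground_truth)

  h <- a$cohort$hospitalizations
  expect_true(all(h$age_years >= 18 & h$age_years <= 104))
  expect_gt(median(h$age_years), 65)
  expect_true(all(h$discharge > h$admit))
  # admissions fall in the four-year study window (chains may run past it)
  expect_gte(min(h$admit), as.POSIXct("2016-01-01", tz = "UTC"))
})
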