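test_that("split sample has the required sizes, is disjoint and seed-reproducible", {
  ids <- paste0("H", 1:10)
  sp <- split_sample(ids, 0.7, seed = 3)
  expect_length(sp$derivation_ids, 7)
  expect_length(sp$validation_ids, 3)
  expect_length(intersect(sp$derivation_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$derivation_ids, sp$validation_ids), ids)
  expect_identical(split_sample(ids, 0.7, seed = 3), sp)
  expect_false(identical(split_sample(ids, 0.7, seed = 4)$derivation_ids,
                         sp$derivation_ids))
  expect_error(split_sample(ids, 0.05, seed = 1), "degenerate")
})

test_that("logistic fit reproduces the closed-form odds ratio of a 2x2 table", {
  X <- matrix(c(rep(1, 100), rep(0, 100)), ncol = 1,
              dimnames = list(NULL, "exposure"))
  y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  fit <- fit_logistic(X, y)
  # saturated one-predictor model: OR = (20*90)/(80*10)
  expect_equal(exp(fit$coefficients[["exposure"]]), 2.25, tolerance = 1e-6)
  expect_equal(fit$intercept, qlogis(0.1), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(unname(fit$ci_95[, "low"]),
               unname(fit$coefficients - 1.96 * fit$standard_errors))
})

test_that("constant outcomes and overparameterized fits are rejected", {
  X <- matrix(rbinom(40, 1, 0.5), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_error(fit_logistic(X, rep(1, 20)), "constant")
  expect_error(fit_logistic(X[1:3, ], c(0, 1, 0)), "observations")
})

test_that("logistic estimates match direct likelihood maximization", {
  set.seed(21)
  for (rep in 1:4) {
    n <- 400
    k <- sample(2:5, 1)
    X <- matrix(rbinom(n * k, 1, 0.3), n, k,
                dimnames = list(NULL, paste0("c", 1:k)))
    beta <- runif(k, -1, 1)
    y <- rbinom(n, 1, plogis(-1 + X %*% beta))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(X, y)
    nll <- function(par) {
      eta <- par[1] + X %*% par[-1]
      -sum(y * eta - log1p(exp(eta)))
    }
    opt <- optim(rep(0, k + 1), nll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    expect_equal(unname(c(fit$intercept, fit$coefficients)), opt$par,
                 tolerance = 1e-5)
  }
})

test_that("separation is flagged honestly instead of silently dropped", {
  set.seed(2)
  X <- cbind(rare = c(rep(1, 4), rep(0, 196)),
             common = rbinom(200, 1, 0.4))
  y <- c(rep(1, 4), rbinom(196, 1, 0.2))  # rare column perfectly predicts
  expect_warning(fit <- fit_logistic(X, y), "separation")
  expect_false(fit$converged)
})

test_that("linear fit is exact on noiseless data and rejects collinearity", {
  set.seed(9)
  X <- matrix(rbinom(300, 1, 0.5), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 1.5 + 2 * X[, "a"]
  fit <- suppressWarnings(fit_linear(X, y))  # zero residuals: perfect-fit warning
  expect_equal(fit$coefficients[["a"]], 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  Xc <- cbind(X, dup = X[, "a"])
  expect_error(fit_linear(Xc, y), "collinear")
})

test_that("null linear model explains essentially no variance", {
  set.seed(31)
  X <- matrix(rbinom(20000 * 5, 1, 0.3), 20000, 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  y <- rnorm(20000)
  expect_lt(fit_linear(X, y)$r_squared, 0.01)
})

test_that("prediction applies frozen coefficients exactly and refuses mismatched columns", {
  set.seed(4)
  X <- matrix(rbinom(600, 1, 0.4), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(-1 + X[, 1] - 0.5 * X[, 2]))
  fit <- fit_logistic(X, y)

  row0 <- matrix(0, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(fit, row0), plogis(fit$intercept))
  row1 <- row0; row1[1, "b"] <- 1
  expect_equal(predict(fit, row1),
               plogis(fit$intercept + fit$coefficients[["b"]]))
  row3 <- matrix(1, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(fit, row3),
               plogis(fit$intercept + sum(fit$coefficients)),
               tolerance = 1e-12)

  # logistic score equation: mean fitted probability = event rate
  expect_equal(mean(predict(fit, X)), mean(y), tolerance = 1e-8)

  Xbad <- X[, c(2, 1, 3)]
  expect_error(predict(fit, Xbad), "do not match")
})

test_that("coefficient table reports odds ratios with significance stars", {
  set.seed(14)
  X <- matrix(rbinom(4000, 1, 0.5), 2000, 2,
              dimnames = list(NULL, c("strong", "null")))
  y <- rbinom(2000, 1, plogis(-1.5 + 1.2 * X[, "strong"]))
  fit <- fit_logistic(X, y)
  tab <- coefficient_table(fit)
  expect_equal(tab$condition, c("strong", "null"))
  expect_equal(tab$estimate, unname(exp(fit$coefficients)))
  expect_equal(tab$stars[tab$condition == "strong"], "***")
  expect_equal(tab$stars[tab$p_value >= 0.05], rep("", sum(tab$p_value >= 0.05)))

  lin <- fit_linear(X, rnorm(2000) + X[, "strong"])
  expect_equal(coefficient_table(lin)$estimate, unname(lin$coefficients))
})

test_that("generator coefficients are recovered within Wald uncertainty", {
  cfg <- generator_config(n = 20000, seed = 77)
  flags <- generate_profiles(cfg)
  labs <- simulate_outcome_labels(flags, cfg)
  conditions <- names(cfg$outcome_models$mortality$coefficients)
  X <- design_matrix(flags, conditions)

  fit <- suppressWarnings(fit_logistic(X, labs$died, "mortality"))
  truth <- cfg$outcome_models$mortality$coefficients
  common <- names(truth)[cfg$prevalences[names(truth)] >= 0.01]
  z <- abs(fit$coefficients[common] - truth[common]) /
    fit$standard_errors[common]
  # ~95% of per-condition estimates should sit within 2 SE of truth
  expect_gte(mean(z < 2), 0.85)

  fitl <- fit_linear(X, labs$log_los, "log_los")
  truth_l <- cfg$los_model$betas
  zl <- abs(fitl$coefficients[common] - truth_l[common]) /
    fitl$standard_errors[common]
  expect_gte(mean(zl < 2), 0.85)
  # noise calibration puts R-squared in the intended regime
  expect_lt(abs(fitl$r_squared - cfg$los_model$target_r2), 0.02)
})
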