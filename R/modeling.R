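# Split-sample derivation/validation and per-outcome model fitting on the
# comorbidity design matrix.

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so package randomness never perturbs user code.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Random derivation/validation split
#'
#' Simple (unstratified) uniform split of hospitalization ids without
#' replacement; the derivation set gets `floor(fraction * n)` ids. The seed
#' is a required, recorded part of the assignment so a run is reproducible.
#'
#' @param ids vector of unique hospitalization ids.
#' @param fraction derivation fraction, strictly between 0 and 1 (default 0.7).
#' @param seed integer seed.
#' @return list of class `elix_split` with `derivation_ids`,
#'   `validation_ids`, `fraction`, `seed`.
#' @examples
#' split_sample(paste0("H", 1:10), fraction = 0.7, seed = 1)
#' @export
split_sample <- function(ids, fraction = 0.7, seed) {
  stopifnot(fraction > 0, fraction < 1, length(ids) >= 2,
            !anyDuplicated(ids))
  n_der <- floor(fraction * length(ids))
  if (n_der < 1 || n_der >= length(ids))
    stop("degenerate split: one of the sets would be empty")
  der <- with_seed(seed, function() sample(ids, n_der))
  structure(list(derivation_ids = der,
                 validation_ids = setdiff(ids, der),
                 fraction = fraction, seed = as.integer(seed)),
            class = "elix_split")
}

#' Build the 0/1 comorbidity design matrix
#'
#' @param flags logical flag matrix (rows in cohort order).
#' @param conditions ordered condition keys from [select_conditions()].
#' @param ids row ids (hospitalization ids).
#' @return numeric 0/1 matrix with rownames `ids` and colnames `conditions`.
#' @export
design_matrix <- function(flags, conditions, ids = rownames(flags)) {
  X <- flags[, conditions, drop = FALSE] * 1
  rownames(X) <- ids
  X
}

# a zero-variance indicator cannot be estimated (and would be silently
# aliased by glm/lm); callers should drop such conditions via min_count
check_constant_columns <- function(X) {
  const <- colnames(X)[apply(X, 2, function(col) length(unique(col)) < 2)]
  if (length(const))
    stop("constant design column(s), drop them before fitting: ",
         paste(const, collapse = ", "))
  invisible(X)
}

new_model <- function(outcome, family, intercept, coefficients, se, p,
                      n_obs, converged, crit = 1.96, extra = list()) {
  ci <- cbind(low = coefficients - crit * se,
              high = coefficients + crit * se)
  rownames(ci) <- names(coefficients)
  structure(c(list(outcome = outcome, family = family,
                   intercept = unname(intercept),
                   coefficients = coefficients, standard_errors = se,
                   ci_95 = ci, p_values = p, n_obs = n_obs,
                   converged = converged),
              extra),
            class = "elix_model")
}

#' Fit a logistic comorbidity model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary outcome on the comorbidity indicators, with Wald standard errors
#' from the observed information. Complete or quasi-complete separation
#' (possible for near-empty conditions such as AIDS/HIV) is detected from
#' runaway coefficients/standard errors; the model is still returned, with
#' `converged = FALSE` and a warning naming the offending columns.
#'
#' @param X 0/1 design matrix from [design_matrix()].
#' @param y logical/0-1 outcome vector, same length as `nrow(X)`.
#' @param outcome label stored on the model (e.g. `"mortality"`).
#' @return an `elix_model` with intercept, per-condition log-odds
#'   coefficients, standard errors, 95% Wald intervals
#'   (`coefficient +/- 1.96 * SE`) and p-values.
#' @export
fit_logistic <- function(X, y, outcome = "binary") {
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2)
    stop("outcome is constant; logistic model needs both classes")
  if (nrow(X) <= ncol(X) + 1)
    stop("more model columns than observations")
  check_constant_columns(X)
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients
  beta <- stats::coef(fit)
  se <- sm[names(beta), "Std. Error"]
  pv <- sm[names(beta), "Pr(>|z|)"]

  unstable <- names(beta)[-1][abs(beta[-1]) > 15 | se[-1] > 10]
  converged <- fit$converged && length(unstable) == 0
  if (length(unstable))
    warning("possible separation; unstable column(s): ",
            paste(unstable, collapse = ", "))

  new_model(outcome, "logistic",
            intercept = beta[1],
            coefficients = beta[-1], se = se[-1], p = pv[-1],
            n_obs = nrow(X), converged = converged,
            extra = list(intercept_se = unname(se[1])))
}

#' Fit the linear log length-of-stay model
#'
#' Ordinary least squares of log length of stay on the comorbidity
#' indicators, with t-based 95% intervals, R-squared and adjusted R-squared.
#'
#' @param X 0/1 design matrix.
#' @param y numeric outcome (log length of stay).
#' @param outcome label stored on the model.
#' @return an `elix_model` (family `"linear"`) carrying `r_squared` and
#'   `adj_r_squared`.
#' @export
fit_linear <- function(X, y, outcome = "log_los") {
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X) + 1)
    stop("more model columns than observations")
  check_constant_columns(X)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sm$coefficients[names(beta), "Std. Error"]
  pv <- sm$coefficients[names(beta), "Pr(>|t|)"]
  crit <- stats::qt(0.975, df = fit$df.residual)
  new_model(outcome, "linear",
            intercept = beta[1],
            coefficients = beta[-1], se = se[-1], p = pv[-1],
            n_obs = nrow(X), converged = TRUE, crit = crit,
            extra = list(intercept_se = unname(se[1]),
                         r_squared = sm$r.squared,
                         adj_r_squared = sm$adj.r.squared,
                         sigma = sm$sigma))
}

#' Score a design matrix with a fitted model
#'
#' Applies frozen coefficients to new rows: the probability
#' `plogis(intercept + X beta)` for logistic models, the linear predictor for
#' linear models. Columns must match the model's conditions exactly, in
#' order; nothing is silently reindexed.
#'
#' @param object an `elix_model`.
#' @param X design matrix with identical columns to the fit.
#' @param ... unused.
#' @return numeric vector, one score per row of `X`.
#' @export
predict.elix_model <- function(object, X, ...) {
  if (!identical(colnames(X), names(object$coefficients)))
    stop("design-matrix columns do not match the model's conditions")
  eta <- drop(object$intercept + X %*% object$coefficients)
  if (object$family == "logistic") stats::plogis(eta) else eta
}

#' @export
print.elix_model <- function(x, ...) {
  cat("<elix_model> outcome=", x$outcome, " family=", x$family,
      " n=", x$n_obs, " converged=", x$converged, "\n", sep = "")
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Formatted coefficient table
#'
#' One row per condition in design-matrix (definition-table) order. Logistic
#' coefficients are reported as odds ratios with `exp(coefficient +/- 1.96 SE)`
#' intervals; linear coefficients as additive effects on the log-day scale.
#' Stars mark Wald p-values below 0.05 / 0.01 / 0.001.
#'
#' @param model an `elix_model`.
#' @return data frame with `condition`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `stars`.
#' @export
coefficient_table <- function(model) {
  est <- model$coefficients
  lo <- model$ci_95[, "low"]
  hi <- model$ci_95[, "high"]
  if (model$family == "logistic") {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  data.frame(condition = names(model$coefficients),
             estimate = unname(est), ci_low = unname(lo),
             ci_high = unname(hi), p_value = unname(model$p_values),
             stars = unname(significance_stars(model$p_values)),
             row.names = NULL, stringsAsFactors = FALSE)
}
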