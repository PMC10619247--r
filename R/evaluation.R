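# Discrimination (c-statistic / ROC, R-squared) and calibration
# (Hosmer-Lemeshow) on derivation and validation sets.

#' Concordance statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen event receives a higher score than a
#' randomly chosen non-event, with ties counted one half. Computed with the
#' rank (Mann-Whitney) formulation, which equals the trapezoidal area under
#' the ROC curve.
#'
#' @param scores numeric predictions.
#' @param labels binary outcomes (logical or 0/1).
#' @return a number in `[0, 1]`.
#' @examples
#' c_statistic(c(0.2, 0.4, 0.4, 0.9), c(0, 0, 1, 1))  # 0.875
#' @export
c_statistic <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("c-statistic undefined: only one outcome class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Receiver operating characteristic curve
#'
#' One operating point per distinct score threshold (no binning), plus the
#' (0,0) and (1,1) anchors. Both coordinates are non-decreasing and the
#' trapezoidal area equals [c_statistic()] exactly.
#'
#' @inheritParams c_statistic
#' @return data frame with columns `fpr`, `tpr` ordered from (0,0) to (1,1),
#'   with the area under the curve in attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("ROC undefined: only one outcome class present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  # after each distinct threshold, counts of events/non-events called positive
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  out <- data.frame(fpr = c(0, fp / n0, 1), tpr = c(0, tp / n1, 1))
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  auc <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) + utils::tail(out$tpr, -1)) / 2)
  attr(out, "auc") <- auc
  out
}

#' Hosmer-Lemeshow calibration test
#'
#' Rows are sorted by predicted probability and cut at group quantiles into
#' (by default) deciles of risk. Tied probabilities are never split across
#' groups - they stay together in the lower group, so group sizes can be
#' unequal. For each group the observed event count `O_g` is compared with
#' the expected count `E_g` (sum of predicted probabilities) via the grouped
#' binomial statistic `sum((O_g - E_g)^2 / (E_g (1 - E_g / n_g)))`, referred
#' to a chi-square distribution with `groups - 2` degrees of freedom.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels binary outcomes.
#' @param groups target number of risk groups (default 10).
#' @return list with `groups` (data frame: `group_index`, `size`, `observed`,
#'   `expected`, `observed_pct`, `expected_pct`), `statistic`, `df`,
#'   `p_value`.
#' @export
hosmer_lemeshow <- function(probs, labels, groups = 10) {
  labels <- as.logical(labels)
  stopifnot(length(probs) == length(labels))
  if (length(probs) < groups)
    stop("need at least as many observations as groups")
  if (any(probs <= 0 | probs >= 1))
    stop("predicted probabilities must lie strictly inside (0, 1)")
  breaks <- unique(stats::quantile(probs, seq(0, 1, length.out = groups + 1),
                                   names = FALSE))
  # (a, b] intervals keep boundary ties together in the lower group
  grp <- cut(probs, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  g <- max(grp)
  size <- tabulate(grp, g)
  observed <- vapply(seq_len(g), function(i) sum(labels[grp == i]), numeric(1))
  expected <- vapply(seq_len(g), function(i) sum(probs[grp == i]), numeric(1))
  denom <- expected * (1 - expected / size)
  if (any(denom <= 0))
    stop("a risk group has expected count 0 or n; try fewer groups")
  statistic <- sum((observed - expected)^2 / denom)
  df <- g - 2
  list(groups = data.frame(group_index = seq_len(g),
                           size = size,
                           observed = as.integer(observed),
                           expected = expected,
                           observed_pct = 100 * observed / size,
                           expected_pct = 100 * expected / size),
       statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Evaluate a fitted model on derivation and validation sets
#'
#' Derivation metrics use the model's own fitted predictions; validation
#' metrics apply the derivation coefficients unchanged (no refit), the
#' split-sample check that a drop in fit would reveal overfitting. Logistic
#' models report c-statistics and Hosmer-Lemeshow calibration for both sets;
#' the linear model reports R-squared, with validation R-squared defined as
#' `1 - SSE/SST` against the validation-sample mean.
#'
#' @param model an `elix_model` fitted on the derivation rows.
#' @param X_derivation,y_derivation derivation design matrix and outcome.
#' @param X_validation,y_validation validation design matrix and outcome.
#' @param hl_groups Hosmer-Lemeshow group count (default 10).
#' @return list of class `elix_evaluation` with `outcome`, `family`, and
#'   either `c_derivation`/`c_validation` plus `hl_derivation`/
#'   `hl_validation`, or `r2_derivation`/`r2_validation`.
#' @export
evaluate_model <- function(model, X_derivation, y_derivation,
                           X_validation, y_validation, hl_groups = 10) {
  p_der <- predict(model, X_derivation)
  p_val <- predict(model, X_validation)
  if (model$family == "logistic") {
    out <- list(outcome = model$outcome, family = model$family,
                c_derivation = c_statistic(p_der, y_derivation),
                c_validation = c_statistic(p_val, y_validation),
                hl_derivation = hosmer_lemeshow(p_der, y_derivation, hl_groups),
                hl_validation = hosmer_lemeshow(p_val, y_validation, hl_groups))
  } else {
    sse <- sum((as.numeric(y_validation) - p_val)^2)
    sst <- sum((as.numeric(y_validation) - mean(as.numeric(y_validation)))^2)
    out <- list(outcome = model$outcome, family = model$family,
                r2_derivation = model$r_squared,
                adj_r2_derivation = model$adj_r_squared,
                r2_validation = 1 - sse / sst)
  }
  structure(out, class = "elix_evaluation")
}

#' @export
print.elix_evaluation <- function(x, ...) {
  cat("<elix_evaluation> outcome=", x$outcome, "\n", sep = "")
  if (x$family == "logistic") {
    cat(sprintf("  c-statistic: derivation %.3f, validation %.3f\n",
                x$c_derivation, x$c_validation))
    cat(sprintf("  Hosmer-Lemeshow (derivation): chi2=%.2f df=%d p=%.3f\n",
                x$hl_derivation$statistic, x$hl_derivation$df,
                x$hl_derivation$p_value))
  } else {
    cat(sprintf("  R-squared: derivation %.3f, validation %.3f\n",
                x$r2_derivation, x$r2_validation))
  }
  invisible(x)
}
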