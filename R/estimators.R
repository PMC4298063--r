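# The two analysis models fitted to each retained sample.

# normal critical value for the 95% interval (z interval, as SEM software
# reports; at ~500 retained subjects the t correction is < 0.2% of the SE)
Z_CRIT <- stats::qnorm(0.975)

#' Ordinary least squares with classical standard errors
#'
#' Shared least-squares core of the two analyses: fits `outcome` on the
#' given regressors plus an intercept via [stats::lm()] and returns the
#' coefficients with homoskedastic standard errors (residual variance with
#' denominator n - p).
#'
#' @param outcome Numeric response vector.
#' @param regressors Numeric matrix or data.frame of regressors (no
#'   intercept column; one is added).
#' @return A list with `coef`, `se` (both named, intercept first),
#'   `sigma` and `df_residual`.
#' @export
fit_ols <- function(outcome, regressors) {
  regressors <- as.data.frame(regressors)
  stopifnot(length(outcome) == nrow(regressors))
  p <- ncol(regressors) + 1L
  if (length(outcome) <= p) {
    stop("need more observations than parameters", call. = FALSE)
  }
  dat <- data.frame(.outcome = outcome, regressors)
  fit <- stats::lm(.outcome ~ ., data = dat)
  if (fit$rank < p) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  ct <- stats::summary.lm(fit)$coefficients
  list(coef = ct[, "Estimate"],
       se = ct[, "Std. Error"],
       sigma = stats::summary.lm(fit)$sigma,
       df_residual = fit$df.residual)
}

new_estimate_result <- function(method, b, se, stability_hat, mean_diff,
                                n_used) {
  structure(
    list(method = method,
         b_pred_hat = b,
         se = se,
         ci_low = b - Z_CRIT * se,
         ci_high = b + Z_CRIT * se,
         stability_hat = stability_hat,
         mean_diff = mean_diff,
         n_used = n_used),
    class = "estimate_result"
  )
}

#' Baseline-adjusted multiple regression
#'
#' Regresses follow-up health on the predictor and baseline health
#' (with intercept) over the retained rows. The predictor coefficient is
#' the estimate of the effect of the predictor on change in health under
#' the assumption that regression toward the mean occurs.
#'
#' @param data A `sample_data`, with attrition already applied (a rate of 0
#'   is fine).
#' @return An `estimate_result`: `b_pred_hat`, its classical `se`, the z
#'   95% interval, the fitted `stability_hat` (baseline coefficient) and
#'   `n_used`.
#' @export
fit_mr <- function(data) {
  d <- retained_data(data)
  fit <- fit_ols(d$h2, d[, c("predictor", "h1")])
  new_estimate_result("mr",
                      b = unname(fit$coef[["predictor"]]),
                      se = unname(fit$se[["predictor"]]),
                      stability_hat = unname(fit$coef[["h1"]]),
                      mean_diff = NA_real_,
                      n_used = nrow(d))
}

#' Change-score analysis
#'
#' Computes change scores as follow-up minus baseline health and regresses
#' them on the predictor (with intercept) over the retained rows; no
#' regression toward the mean is assumed. Also reports the retained-sample
#' mean change score (`mean_diff`), whose population value is zero.
#'
#' @inheritParams fit_mr
#' @return An `estimate_result` with `mean_diff` filled in and
#'   `stability_hat` set to `NA`.
#' @export
fit_change_score <- function(data) {
  d <- retained_data(data)
  change <- d$h2 - d$h1
  fit <- fit_ols(change, d[, "predictor", drop = FALSE])
  new_estimate_result("change_score",
                      b = unname(fit$coef[["predictor"]]),
                      se = unname(fit$se[["predictor"]]),
                      stability_hat = NA_real_,
                      mean_diff = mean(change),
                      n_used = nrow(d))
}

#' @export
print.estimate_result <- function(x, digits = 4, ...) {
  cat(if (x$method == "mr") "Baseline-adjusted regression"
      else "Change-score analysis",
      " (n = ", x$n_used, ")\n", sep = "")
  cat("  b_pred = ", format(x$b_pred_hat, digits = digits),
      " (SE ", format(x$se, digits = digits), "), 95% CI [",
      format(x$ci_low, digits = digits), ", ",
      format(x$ci_high, digits = digits), "]\n", sep = "")
  if (!is.na(x$stability_hat)) {
    cat("  baseline coefficient =",
        format(x$stability_hat, digits = digits), "\n")
  }
  if (!is.na(x$mean_diff)) {
    cat("  mean change score =", format(x$mean_diff, digits = digits), "\n")
  }
  invisible(x)
}
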