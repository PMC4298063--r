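# Analytic estimands: the population value of each fitted coefficient,
# with and without selection, computed purely from moments. These serve as
# the N -> infinity oracle for every Monte Carlo cell and are deliberately
# independent of the simulator's RNG.

as_study_cov <- function(x) {
  if (inherits(x, "population_spec")) x <- implied_covariance(x)
  if (inherits(x, "selection_moments")) x <- x$cov
  x <- unclass(x)
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("expected a covariance matrix, a population_spec or selection_moments",
         call. = FALSE)
  }
  need <- c("predictor", "h1", "h2")
  if (is.null(dimnames(x)) && nrow(x) >= 3L) {
    # unlabeled matrices are taken in the canonical variable order
    nm <- STUDY_VARS[seq_len(nrow(x))]
    dimnames(x) <- list(nm, nm)
  }
  if (!all(need %in% rownames(x))) {
    stop("covariance must cover (predictor, h1, h2)", call. = FALSE)
  }
  x[need, need]
}

#' Population coefficients of the baseline-adjusted regression
#'
#' Partial regression coefficients of follow-up health on the predictor and
#' baseline health, from a (possibly selection-distorted, possibly
#' non-unit-variance) covariance matrix via the normal equations.
#'
#' @param cov A covariance matrix over at least `(predictor, h1, h2)`, a
#'   [population_spec()] or a [selection_moments()] object.
#' @return Named numeric vector with elements `predictor` and `h1`.
#' @export
mr_coefficients <- function(cov) {
  s <- as_study_cov(cov)
  a <- s[c("predictor", "h1"), c("predictor", "h1")]
  if (abs(det(a)) < 1e-12) {
    stop("predictor/baseline covariance block is singular", call. = FALSE)
  }
  drop(solve(a, s[c("predictor", "h1"), "h2"]))
}

#' Multiple-regression estimand
#'
#' The population value of the predictor coefficient in the regression of
#' follow-up health on predictor and baseline health. In a transient
#' population without selection this equals `b_pred` exactly, for any
#' loading and stability: baseline adjustment builds the occurring
#' regression toward the mean into the model.
#'
#' @inheritParams mr_coefficients
#' @return A scalar.
#' @export
#' @examples
#' mr_estimand(population_spec("transient"))  # 0.10 exactly
#' mr_estimand(population_spec("enduring"))   # 0.169: inappropriate use
mr_estimand <- function(cov) {
  unname(mr_coefficients(cov)[["predictor"]])
}

#' Change-score estimand
#'
#' The population value of the coefficient in the regression of
#' (follow-up health - baseline health) on the predictor:
#' cov(h2 - h1, predictor) / var(predictor). In an enduring population
#' without selection this equals `b_pred` exactly for any loading and
#' stability; in a transient population it is biased by the
#' predictor-correlated regression toward the mean
#' (`b_pred - stability * loading^2` at the defaults).
#'
#' @inheritParams mr_coefficients
#' @return A scalar.
#' @export
#' @examples
#' cs_estimand(population_spec("enduring"))   # 0.10 exactly
#' cs_estimand(population_spec("transient"))  # 0.02: inappropriate use
cs_estimand <- function(cov) {
  s <- as_study_cov(cov)
  if (s["predictor", "predictor"] <= 0) {
    stop("predictor variance must be positive", call. = FALSE)
  }
  unname((s["predictor", "h2"] - s["predictor", "h1"]) /
           s["predictor", "predictor"])
}

#' Conditional moments of the retained subpopulation
#'
#' Analytic counterpart of deleting the fraction `rate` of subjects with the
#' highest liability of dropping out: moments of the study variables
#' conditional on the liability falling below its (1 - rate) quantile.
#' With standardized liability L, threshold t = qnorm(1 - rate) and inverse
#' Mills ratio m = dnorm(t) / pnorm(t), incidental truncation gives
#' E\[X | L < t\] = -m * cov(X, L) and
#' Cov\[X | L < t\] = Cov(X) - (t*m + m^2) * cov(X, L) cov(X, L)'.
#'
#' @param spec A [population_spec()].
#' @param rate Attrition rate in `[0, 1)`.
#' @return An object of class `selection_moments`: a list with the retained
#'   fraction, the truncation `threshold`, the conditional `mean` and
#'   conditional covariance `cov` over all four study variables.
#' @export
#' @examples
#' sm <- selection_moments(population_spec("transient", "mnar-strong"), 0.5)
#' sm$mean[["liability"]]               # -0.798: half-normal mean
#' sm$cov["liability", "liability"]     # 0.363
selection_moments <- function(spec, rate) {
  stopifnot(inherits(spec, "population_spec"),
            is.numeric(rate), length(rate) == 1L)
  if (rate < 0 || rate >= 1) {
    stop("attrition rate must be in [0, 1)", call. = FALSE)
  }
  sigma <- unclass(implied_covariance(spec))
  if (rate == 0) {
    return(structure(
      list(rate = 0, retained_fraction = 1, threshold = Inf,
           mean = stats::setNames(rep(0, 4), STUDY_VARS), cov = sigma),
      class = "selection_moments"
    ))
  }
  t <- stats::qnorm(1 - rate)
  m <- stats::dnorm(t) / stats::pnorm(t)
  gamma <- sigma[, "liability"]
  cond_cov <- sigma - (t * m + m^2) * tcrossprod(gamma)
  structure(
    list(rate = rate, retained_fraction = 1 - rate, threshold = t,
         mean = -m * gamma, cov = (cond_cov + t(cond_cov)) / 2),
    class = "selection_moments"
  )
}

#' @export
print.selection_moments <- function(x, digits = 4, ...) {
  cat("Retained-subpopulation moments (attrition rate ", format(x$rate),
      ", liability threshold ", format(x$threshold, digits = digits),
      ")\n", sep = "")
  cat("conditional means:\n")
  print(round(x$mean, digits))
  cat("conditional covariance:\n")
  print(round(x$cov, digits))
  invisible(x)
}

#' Asymptotic estimand under selective attrition
#'
#' Composes [selection_moments()] with [mr_estimand()] or [cs_estimand()]:
#' the expected coefficient, as the sample size grows, of an analysis run on
#' the subjects retained after deleting the top `rate` fraction of the
#' liability distribution. The fixed-quantile truncation used here differs
#' from the simulator's top-k deletion by O(1/sqrt(N)).
#'
#' @param spec A [population_spec()].
#' @param method `"mr"` or `"change_score"`.
#' @param rate Attrition rate in `[0, 1)`.
#' @return A scalar.
#' @export
#' @examples
#' attrition_estimand(population_spec("transient", "mnar-strong"), "mr", 0.5)
attrition_estimand <- function(spec, method = c("mr", "change_score"),
                               rate = 0) {
  method <- match.arg(method)
  sm <- selection_moments(spec, rate)
  if (method == "mr") mr_estimand(sm) else cs_estimand(sm)
}

#' Expected mean change score in the retained subpopulation
#'
#' The asymptotic value of the average (follow-up - baseline) health score
#' among retained subjects; zero without selection or under MCAR attrition,
#' and displaced whenever attrition is more strongly tied to health at one
#' time point than the other.
#'
#' @inheritParams attrition_estimand
#' @return A scalar.
#' @export
diff_estimand <- function(spec, rate = 0) {
  sm <- selection_moments(spec, rate)
  unname(sm$mean[["h2"]] - sm$mean[["h1"]])
}

#' Closed-form estimand grid
#'
#' Tabulates the asymptotic coefficient for every combination of population,
#' dropout scenario, attrition rate and analysis method, flagging the
#' appropriate-method cells (MR in transient populations, change scores in
#' enduring ones), where the no-attrition estimand equals the true effect
#' exactly.
#'
#' @param rates Attrition rates to evaluate.
#' @param scenarios Dropout scenario ids (see [dropout_scenarios()]).
#' @param sign_variant `"positive"` or `"negative"`.
#' @param ... Passed on to [population_spec()] (e.g. `loading`, `stability`,
#'   `b_pred`).
#' @return A data.frame with one row per
#'   (cause_type, scenario, rate, method) cell: the `estimand`, the mean
#'   change-score displacement `diff` (change-score cells only), the
#'   `appropriate` flag and the `true_effect`.
#' @export
estimand_grid <- function(rates = c(0, 0.3, 0.5, 0.7),
                          scenarios = names(dropout_scenarios()),
                          sign_variant = "positive", ...) {
  rows <- list()
  for (cause in c("transient", "enduring")) {
    for (scen in scenarios) {
      spec <- population_spec(cause, scen, sign_variant, ...)
      for (rate in rates) {
        sm <- selection_moments(spec, rate)
        for (method in c("mr", "change_score")) {
          est <- if (method == "mr") mr_estimand(sm) else cs_estimand(sm)
          rows[[length(rows) + 1L]] <- data.frame(
            cause_type = cause, scenario = scen, sign = sign_variant,
            rate = rate, method = method,
            appropriate = (cause == "transient") == (method == "mr"),
            estimand = est,
            diff = if (method == "change_score")
              unname(sm$mean[["h2"]] - sm$mean[["h1"]]) else NA_real_,
            true_effect = true_effect(spec),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}
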