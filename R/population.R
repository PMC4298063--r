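# Structural population models for the attrition / RTM simulation study.
#
# Every population has four standardized variables, stored everywhere in the
# fixed order (predictor, h1, h2, liability):
#   predictor — baseline predictor of change
#   h1        — health measure at baseline
#   h2        — health measure at follow-up
#   liability — latent liability of dropping out (drives listwise deletion)
# plus one latent common cause of the predictor/baseline-health association.
# All five structural shocks are independent standard normals and every
# variable is scaled to unit variance, so path coefficients are standardized
# regression weights.

STUDY_VARS <- c("predictor", "h1", "h2", "liability")
STUDY_SHOCKS <- c("cause", "e_predictor", "e_h1", "e_h2", "e_liability")

#' Canonical dropout-dependency scenarios
#'
#' The four scenarios of the study, as regressions of the liability of
#' dropping out on (predictor, baseline health, follow-up health):
#' `mcar` (0, 0, 0) — attrition completely at random; `mar` (.3, .3, 0) —
#' dependent on baseline variables only; `mnar-weak` (.3, .3, .1) and
#' `mnar-strong` (.3, .3, .3) — additionally dependent on the unobserved
#' follow-up score.
#'
#' @return Named list of length-3 coefficient vectors
#'   `(predictor, h1, h2)`.
#' @export
#' @examples
#' dropout_scenarios()[["mnar-strong"]]
dropout_scenarios <- function() {
  list(
    "mcar"        = c(predictor = 0.0, h1 = 0.0, h2 = 0.0),
    "mar"         = c(predictor = 0.3, h1 = 0.3, h2 = 0.0),
    "mnar-weak"   = c(predictor = 0.3, h1 = 0.3, h2 = 0.1),
    "mnar-strong" = c(predictor = 0.3, h1 = 0.3, h2 = 0.3)
  )
}

resolve_dropout <- function(dropout) {
  if (is.character(dropout) && length(dropout) == 1L) {
    if (dropout == "none") dropout <- "mcar"
    scen <- dropout_scenarios()
    if (!dropout %in% names(scen)) {
      stop("unknown dropout scenario '", dropout, "'; known scenarios: ",
           paste(names(scen), collapse = ", "),
           " (or give an explicit coefficient triple)", call. = FALSE)
    }
    return(list(id = dropout, b_drop = scen[[dropout]]))
  }
  if (is.numeric(dropout) && length(dropout) == 3L) {
    b <- as.numeric(dropout)
    names(b) <- c("predictor", "h1", "h2")
    scen <- dropout_scenarios()
    hit <- vapply(scen, function(s) isTRUE(all.equal(unname(s), unname(b))),
                  logical(1))
    id <- if (any(hit)) names(scen)[which(hit)[1L]] else "custom"
    return(list(id = id, b_drop = b))
  }
  stop("'dropout' must be a scenario id or a numeric coefficient triple",
       call. = FALSE)
}

#' Define a structural population for the simulation study
#'
#' Builds a fully solved population model. In a `transient` population the
#' latent common cause loads equally on the predictor and baseline health
#' but has no direct path to follow-up health, so it produces rank-order
#' instability (regression toward the mean) that is correlated with the
#' predictor; baseline-adjusted multiple regression is the appropriate
#' analysis. In an `enduring` population the cause additionally has a direct
#' path to follow-up health, sized so that its total effect on follow-up
#' health equals its effect on baseline health — it produces no
#' predictor-correlated RTM and change-score analysis is appropriate.
#'
#' The liability of dropping out is regressed on the three study variables
#' with the `dropout` coefficients and given its own residual. Residual
#' variances of all four variables are solved so that every variable has
#' unit variance; parametrizations that would require a non-positive
#' residual variance are rejected.
#'
#' The `negative` sign variant flips the sign of the cause-to-predictor
#' loading, the predictor-to-follow-up path and the predictor-to-liability
#' path, turning the predictor into a protective factor; the implied
#' covariance is the positive variant's with every predictor row/column
#' negated, and the true effect of the predictor on change becomes
#' `-b_pred`. Its reduced form additionally negates the predictor's
#' residual loading, so a negative-variant sample generated from the same
#' seed as a positive-variant one is its exact mirror image
#' (common-random-numbers coupling for sign contrasts; the sampling
#' distribution is unaffected).
#'
#' @param cause_type `"transient"` or `"enduring"`.
#' @param dropout A scenario id (see [dropout_scenarios()]), `"none"` as an
#'   alias for `"mcar"`, or a numeric coefficient triple
#'   `(predictor, h1, h2)`.
#' @param sign_variant `"positive"` (default) or `"negative"`.
#' @param loading Standardized loading of the latent cause on baseline
#'   health and (up to sign) on the predictor. Default 0.4, giving a
#'   baseline predictor–health correlation of 0.16.
#' @param stability Path from baseline to follow-up health. Default 0.50.
#' @param b_pred Direct effect of the predictor on follow-up health — the
#'   true effect of the predictor on change. Default 0.10.
#' @param enduring_direct Direct path from the cause to follow-up health.
#'   `NULL` (default) solves it structurally: 0 for transient populations
#'   and `loading * (1 - stability)` for enduring ones, which makes the
#'   cause's total effect on follow-up equal its effect on baseline.
#' @return An object of class `population_spec`.
#' @seealso [implied_covariance()], [generate_sample()]
#' @export
#' @examples
#' spec <- population_spec("transient", "mcar")
#' spec$resid[["predictor"]]  # 1 - 0.4^2 = 0.84
#' population_spec("enduring", "mnar-strong")$enduring_direct  # 0.2
population_spec <- function(cause_type = c("transient", "enduring"),
                            dropout = "mcar",
                            sign_variant = c("positive", "negative"),
                            loading = 0.4,
                            stability = 0.5,
                            b_pred = 0.1,
                            enduring_direct = NULL) {
  cause_type <- match.arg(cause_type)
  sign_variant <- match.arg(sign_variant)
  stopifnot(is.numeric(loading), length(loading) == 1L,
            is.numeric(stability), length(stability) == 1L,
            is.numeric(b_pred), length(b_pred) == 1L)
  drp <- resolve_dropout(dropout)
  sgn <- if (sign_variant == "negative") -1 else 1

  if (is.null(enduring_direct)) {
    d <- if (cause_type == "enduring") loading * (1 - stability) else 0
  } else {
    d <- enduring_direct
    if (cause_type == "transient" && d != 0) {
      stop("a transient population has no direct cause-to-follow-up path; ",
           "'enduring_direct' must be 0", call. = FALSE)
    }
  }

  # Reduced form: each variable as a linear combination of the five
  # independent standard-normal shocks. Residual loadings are solved so
  # each row has unit squared norm (unit implied variance).
  rf <- matrix(0, 4, 5, dimnames = list(STUDY_VARS, STUDY_SHOCKS))
  solve_residual <- function(explained, var) {
    r <- 1 - sum(explained^2)
    if (r <= 0) {
      stop("residual variance of '", var, "' is non-positive (",
           format(r), "); the parametrization is inadmissible", call. = FALSE)
    }
    r
  }

  # The negative variant negates the predictor's residual loading as well,
  # so that with common shocks its draws are the exact mirror image
  # (predictor -> -predictor) of the positive variant's draws. This is
  # common-random-numbers coupling for variant contrasts; the joint
  # distribution is unchanged (the residual shock is symmetric).
  v_pred <- c(sgn * loading, 0, 0, 0, 0)
  resid_pred <- solve_residual(v_pred, "predictor")
  v_pred[2L] <- sgn * sqrt(resid_pred)

  v_h1 <- c(loading, 0, 0, 0, 0)
  resid_h1 <- solve_residual(v_h1, "h1")
  v_h1[3L] <- sqrt(resid_h1)

  v_h2 <- stability * v_h1 + sgn * b_pred * v_pred + c(d, 0, 0, 0, 0)
  resid_h2 <- solve_residual(v_h2, "h2")
  v_h2[4L] <- sqrt(resid_h2)

  b_drop <- drp$b_drop
  v_liab <- sgn * b_drop[["predictor"]] * v_pred +
    b_drop[["h1"]] * v_h1 + b_drop[["h2"]] * v_h2
  resid_liab <- solve_residual(v_liab, "liability")
  v_liab[5L] <- sqrt(resid_liab)

  rf["predictor", ] <- v_pred
  rf["h1", ] <- v_h1
  rf["h2", ] <- v_h2
  rf["liability", ] <- v_liab

  structure(
    list(
      cause_type = cause_type,
      scenario = drp$id,
      sign_variant = sign_variant,
      loading = loading,
      stability = stability,
      b_pred = b_pred,
      enduring_direct = d,
      b_drop = b_drop,
      resid = c(predictor = resid_pred, h1 = resid_h1,
                h2 = resid_h2, liability = resid_liab),
      reduced_form = rf
    ),
    class = "population_spec"
  )
}

#' True effect of the predictor on change in health
#'
#' The signed population value against which every fitted coefficient is
#' compared: `b_pred` in the positive variant, `-b_pred` in the negative one.
#'
#' @param spec A [population_spec()].
#' @return A scalar.
#' @export
true_effect <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$sign_variant == "negative") -spec$b_pred else spec$b_pred
}

#' Model-implied covariance matrix of a population
#'
#' Computes the exact covariance of (predictor, h1, h2, liability) from the
#' linear-Gaussian reduced form: the matrix of total effects of the
#' independent exogenous shocks times its transpose. All four variables are
#' standardized, so the result has a unit diagonal and off-diagonal entries
#' are correlations.
#'
#' For the default transient population this gives the path-tracing values
#' cov(predictor, h1) = loading^2, cov(predictor, h2) =
#' stability * loading^2 + b_pred and cov(h1, h2) =
#' stability + b_pred * loading^2.
#'
#' @param spec A [population_spec()].
#' @return A symmetric 4x4 matrix of class `implied_covariance` with
#'   dimnames `(predictor, h1, h2, liability)`.
#' @export
#' @examples
#' implied_covariance(population_spec("transient"))["predictor", "h1"]  # 0.16
implied_covariance <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  rf <- spec$reduced_form
  m <- rf %*% t(rf)
  m <- (m + t(m)) / 2
  structure(m, class = c("implied_covariance", class(m)))
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Structural population (", x$cause_type, " causes, ",
      x$sign_variant, " variant)\n", sep = "")
  cat("  dropout scenario: ", x$scenario, "  b_drop = (",
      paste(format(x$b_drop), collapse = ", "), ")\n", sep = "")
  cat("  loading ", format(x$loading),
      ", stability ", format(x$stability),
      ", b_pred ", format(x$b_pred),
      ", enduring direct ", format(x$enduring_direct), "\n", sep = "")
  cat("  residual variances:",
      paste(names(x$resid), format(x$resid, digits = 4), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.implied_covariance <- function(x, digits = 4, ...) {
  cat("Model-implied covariance (standardized variables)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Serialize a population spec to a flat key:value list
#'
#' The companion of [population_spec_from_config()]; together they round-trip
#' a spec through a flat plain-text config block.
#'
#' @param spec A [population_spec()].
#' @return A named list of scalars (the dropout triple is flattened into
#'   `b_drop_predictor`, `b_drop_h1`, `b_drop_h2`).
#' @export
population_spec_config <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  list(
    cause_type = spec$cause_type,
    sign_variant = spec$sign_variant,
    loading = spec$loading,
    stability = spec$stability,
    b_pred = spec$b_pred,
    b_drop_predictor = unname(spec$b_drop[["predictor"]]),
    b_drop_h1 = unname(spec$b_drop[["h1"]]),
    b_drop_h2 = unname(spec$b_drop[["h2"]])
  )
}

#' Rebuild a population spec from a flat key:value list
#'
#' @param config A named list as produced by [population_spec_config()].
#' @return A [population_spec()].
#' @export
population_spec_from_config <- function(config) {
  population_spec(
    cause_type = config$cause_type,
    dropout = c(config$b_drop_predictor, config$b_drop_h1, config$b_drop_h2),
    sign_variant = config$sign_variant,
    loading = config$loading,
    stability = config$stability,
    b_pred = config$b_pred
  )
}
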