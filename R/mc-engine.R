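# Monte Carlo engine: runs the full factorial study
# (population x dropout scenario x attrition rate x method x sign variant)
# and aggregates replicates into per-cell summaries.

#' Study configuration
#'
#' Bundles everything the Monte Carlo engine needs. The defaults are the
#' study conditions: 500 replicates of N = 1000, attrition rates 30/50/70%
#' for appropriate-method cells, 50% only for inappropriate-method and
#' negative-variant cells, all four dropout scenarios, and a true effect of
#' 0.10 (flipped to -0.10 in negative variants).
#'
#' @param master_seed Single master seed; every replicate seed is derived
#'   from it (see Details).
#' @param replicates Number of replicate samples per cell.
#' @param n Subjects per replicate before attrition.
#' @param rates Attrition rates for appropriate-method cells.
#' @param inappropriate_rates Attrition rates for inappropriate-method and
#'   negative-variant cells.
#' @param scenarios Dropout scenario ids (see [dropout_scenarios()]).
#' @param b_pred,loading,stability Structural parameters passed to
#'   [population_spec()].
#' @param include_negative Include the negative-sign-variant
#'   inappropriate-method cells.
#'
#' @details Replicate r of the population stream s uses the seed
#' `(master_seed * 1000003 + s * 10007 + r) mod (2^31 - 1)`, so any
#' replicate is reproducible in isolation. A stream is one
#' (cause type, dropout scenario) population: methods, attrition rates and
#' sign variants share replicate shocks, so analyses are compared on
#' matched draws.
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(master_seed = 1L,
                         replicates = 500L,
                         n = 1000L,
                         rates = c(0.3, 0.5, 0.7),
                         inappropriate_rates = 0.5,
                         scenarios = names(dropout_scenarios()),
                         b_pred = 0.1,
                         loading = 0.4,
                         stability = 0.5,
                         include_negative = TRUE) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            replicates >= 1, n >= 10,
            all(rates >= 0 & rates < 1),
            all(inappropriate_rates >= 0 & inappropriate_rates < 1),
            !anyDuplicated(scenarios))
  structure(
    list(master_seed = as.integer(master_seed),
         replicates = as.integer(replicates),
         n = as.integer(n),
         rates = rates,
         inappropriate_rates = inappropriate_rates,
         scenarios = scenarios,
         b_pred = b_pred,
         loading = loading,
         stability = stability,
         include_negative = isTRUE(include_negative)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Monte Carlo study configuration\n")
  cat("  master seed", x$master_seed, "|", x$replicates, "replicates of n =",
      x$n, "\n")
  cat("  appropriate-method rates:", paste(x$rates, collapse = ", "), "\n")
  cat("  inappropriate-method rates:",
      paste(x$inappropriate_rates, collapse = ", "), "\n")
  cat("  scenarios:", paste(x$scenarios, collapse = ", "),
      "| negative variants:", x$include_negative, "\n")
  cat("  loading", x$loading, ", stability", x$stability,
      ", b_pred", x$b_pred, "\n")
  invisible(x)
}

# One integer stream per (cause type, scenario) population. Sign variants
# deliberately share a stream: the negative variant re-uses the positive
# variant's exogenous shocks, so sign-antisymmetry contrasts are computed
# on matched draws, as are method contrasts within a scenario.
stream_id <- function(spec) {
  pop <- as.integer(spec$cause_type == "enduring")
  scen <- match(spec$scenario, names(dropout_scenarios()))
  if (is.na(scen)) scen <- 9L
  pop * 16L + scen
}

derive_replicate_seed <- function(master_seed, stream, r) {
  # all terms stay well below 2^53, so the double arithmetic is exact
  as.integer(((master_seed %% 2147483647) * 1000003 +
                stream * 10007 + r) %% 2147483647)
}

#' Confidence-interval coverage
#'
#' Fraction of estimates whose 95% interval contains the true value
#' (closed endpoints).
#'
#' @param estimates List of `estimate_result` objects, or a data.frame with
#'   columns `ci_low` and `ci_high`.
#' @param true_value The generating population value.
#' @return A fraction in `[0, 1]`.
#' @export
coverage <- function(estimates, true_value) {
  if (is.data.frame(estimates)) {
    lo <- estimates$ci_low
    hi <- estimates$ci_high
  } else {
    if (length(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
    lo <- vapply(estimates, `[[`, numeric(1), "ci_low")
    hi <- vapply(estimates, `[[`, numeric(1), "ci_high")
  }
  if (length(lo) == 0L) stop("no estimates supplied", call. = FALSE)
  mean(lo <= true_value & true_value <= hi)
}

#' Run one cell of the study
#'
#' Loops replicates: generate a sample, apply attrition, fit the analysis;
#' then aggregates the mean coefficient, mean SE, 95% CI coverage against
#' the true effect, and (for change scores) the mean change score.
#' Deterministic given the configuration's master seed.
#'
#' @param spec A [population_spec()].
#' @param method `"mr"` or `"change_score"`.
#' @param rate Attrition rate in `[0, 1)`.
#' @param config A [study_config()].
#' @param keep_replicates Also return the per-replicate estimates.
#' @return A one-row data.frame (columns `scenario`, `cause_type`,
#'   `method`, `appropriate`, `sign`, `rate`, `reps`, `n`, `mean_b`,
#'   `mean_se`, `coverage_pct`, `mean_diff`, `mc_se_b`, `master_seed`);
#'   with `keep_replicates = TRUE`, a list with the summary and a
#'   `replicates` data.frame.
#' @export
#' @examples
#' cfg <- study_config(master_seed = 1, replicates = 20, n = 400)
#' run_cell(population_spec("transient", "mcar"), "mr", 0.5, cfg)
run_cell <- function(spec, method = c("mr", "change_score"), rate, config,
                     keep_replicates = FALSE) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(config, "study_config"))
  method <- match.arg(method)
  fit_fun <- if (method == "mr") fit_mr else fit_change_score
  stream <- stream_id(spec)
  reps <- config$replicates

  b <- se <- lo <- hi <- diffs <- numeric(reps)
  for (r in seq_len(reps)) {
    est <- tryCatch({
      seed <- derive_replicate_seed(config$master_seed, stream, r)
      s <- generate_sample(spec, config$n, seed, replicate_id = r)
      s <- apply_attrition(s, rate)
      fit_fun(s)
    }, error = function(e) {
      stop("replicate ", r, " failed: ", conditionMessage(e), call. = FALSE)
    })
    b[r] <- est$b_pred_hat
    se[r] <- est$se
    lo[r] <- est$ci_low
    hi[r] <- est$ci_high
    diffs[r] <- est$mean_diff
  }

  truth <- true_effect(spec)
  summary <- data.frame(
    scenario = spec$scenario,
    cause_type = spec$cause_type,
    method = method,
    appropriate = (spec$cause_type == "transient") == (method == "mr"),
    sign = spec$sign_variant,
    rate = rate,
    reps = reps,
    n = config$n,
    mean_b = mean(b),
    mean_se = mean(se),
    coverage_pct = 100 * mean(lo <= truth & truth <= hi),
    mean_diff = if (method == "change_score") mean(diffs) else NA_real_,
    mc_se_b = stats::sd(b) / sqrt(reps),
    master_seed = config$master_seed,
    stringsAsFactors = FALSE
  )
  if (!keep_replicates) return(summary)
  list(summary = summary,
       replicates = data.frame(replicate = seq_len(reps), b_pred_hat = b,
                               se = se, ci_low = lo, ci_high = hi,
                               mean_diff = diffs))
}

#' Run the full factorial study
#'
#' Emits every cell of the study design: for each dropout scenario, the
#' appropriate analyses (MR in the transient population, change scores in
#' the enduring one) at each configured attrition rate, the inappropriate
#' analyses (methods swapped between populations) at the inappropriate-cell
#' rates, and — if enabled — the negative-sign-variant inappropriate
#' analyses.
#'
#' @param config A [study_config()].
#' @return A data.frame of cell summaries (see [run_cell()]), one row per
#'   cell, tagged so every published table row is addressable by
#'   `(scenario, cause_type, method, sign, rate)`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  plan <- list()
  add <- function(cause, method, sign, rates) {
    for (scen in config$scenarios) {
      for (rate in rates) {
        plan[[length(plan) + 1L]] <<- list(cause = cause, scen = scen,
                                           method = method, sign = sign,
                                           rate = rate)
      }
    }
  }
  add("transient", "mr", "positive", config$rates)
  add("enduring", "change_score", "positive", config$rates)
  add("enduring", "mr", "positive", config$inappropriate_rates)
  add("transient", "change_score", "positive", config$inappropriate_rates)
  if (config$include_negative) {
    add("enduring", "mr", "negative", config$inappropriate_rates)
    add("transient", "change_score", "negative", config$inappropriate_rates)
  }

  cells <- lapply(plan, function(p) {
    spec <- population_spec(p$cause, p$scen, p$sign,
                            loading = config$loading,
                            stability = config$stability,
                            b_pred = config$b_pred)
    run_cell(spec, p$method, p$rate, config)
  })
  do.call(rbind, cells)
}
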