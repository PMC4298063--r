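# Replicate-level data generation and listwise-deletion attrition.

#' Draw one replicate sample from a structural population
#'
#' Draws independent standard-normal exogenous shocks (the latent cause and
#' the four residuals) and builds the study variables through the
#' population's structural equations. The result is deterministic given
#' `(spec, n, seed)` and leaves the caller's RNG state untouched. No
#' attrition is applied; all rows are flagged as retained.
#'
#' @param spec A [population_spec()].
#' @param n Number of subjects (at least 10).
#' @param seed Non-negative integer seed for this replicate.
#' @param replicate_id Optional identifier carried into dumped output.
#' @return A `sample_data` data.frame with columns `predictor`, `h1`, `h2`,
#'   `liability` and logical `retained`, and attributes `seed`, `n_total`,
#'   `replicate_id` and `attrition_rate` (`NA` until [apply_attrition()]).
#' @export
#' @examples
#' s <- generate_sample(population_spec("transient"), n = 500, seed = 7)
#' cor(s$predictor, s$h1)  # near 0.16
generate_sample <- function(spec, n, seed, replicate_id = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 10) {
    stop("'n' must be a single number >= 10", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0) {
    stop("'seed' must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  shocks <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(n * 5L), nrow = n, ncol = 5L)
  })
  x <- shocks %*% t(spec$reduced_form)
  out <- as.data.frame(x)
  names(out) <- STUDY_VARS
  out$retained <- TRUE
  structure(out,
            class = c("sample_data", "data.frame"),
            spec = spec,
            seed = as.integer(seed),
            n_total = n,
            replicate_id = replicate_id,
            attrition_rate = NA_real_)
}

# round-half-away-from-zero; with n = 1000 and rates .3/.5/.7 it is exact
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Induce selective attrition by listwise deletion
#'
#' Flags the `round(rate * n)` rows with the largest liability of dropping
#' out as dropped (ties, a probability-zero event for continuous draws,
#' broken by row order). Rows are kept in place with their `retained` flag
#' cleared so the full sample remains auditable; analyses use only retained
#' rows.
#'
#' @param data A `sample_data` from [generate_sample()] without prior
#'   attrition.
#' @param rate Attrition rate in `[0, 1)`.
#' @return The `sample_data` with `retained` flags set and the
#'   `attrition_rate` attribute recorded.
#' @export
apply_attrition <- function(data, rate) {
  stopifnot(inherits(data, "sample_data"))
  if (!is.na(attr(data, "attrition_rate"))) {
    stop("attrition has already been applied to this sample", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    stop("attrition rate must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(data)
  k <- as.integer(round_half_away(rate * n))
  if (k > 0L) {
    dropped <- order(data$liability, decreasing = TRUE)[seq_len(k)]
    data$retained[dropped] <- FALSE
  }
  attr(data, "attrition_rate") <- rate
  data
}

#' Retained rows of a sample
#'
#' @param data A `sample_data`.
#' @return A plain data.frame with only the retained rows.
#' @export
retained_data <- function(data) {
  stopifnot(inherits(data, "sample_data"))
  as.data.frame(data)[data$retained, , drop = FALSE]
}

#' @export
print.sample_data <- function(x, ...) {
  rate <- attr(x, "attrition_rate")
  cat("Simulated sample: n =", attr(x, "n_total"),
      "| seed =", attr(x, "seed"),
      if (is.na(rate)) "| no attrition applied"
      else paste0("| attrition rate = ", rate,
                  " (", sum(x$retained), " retained)"), "\n")
  utils::str(as.data.frame(x), give.attr = FALSE)
  invisible(x)
}

#' Dump a replicate as delimited text
#'
#' Writes one row per subject with columns
#' `(replicate, seed, predictor, h1, h2, liability, retained)`,
#' tab-separated with a header.
#'
#' @param data A `sample_data`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(data, path) {
  stopifnot(inherits(data, "sample_data"))
  out <- data.frame(
    replicate = attr(data, "replicate_id"),
    seed = attr(data, "seed"),
    as.data.frame(data)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
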