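# Configuration files, result export, rendered tables and the run manifest.

#' Read a study configuration from a flat key:value file
#'
#' The file is flat YAML (one `key: value` per line); unknown keys are
#' rejected. `rates`, `inappropriate_rates` and `scenarios` may be
#' comma-separated strings or YAML sequences.
#'
#' @param path Config file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  split_num <- function(x) {
    if (is.character(x)) as.numeric(strsplit(x, ",[ ]*")[[1]]) else x
  }
  for (k in c("rates", "inappropriate_rates")) {
    if (!is.null(raw[[k]])) raw[[k]] <- split_num(raw[[k]])
  }
  if (!is.null(raw$scenarios) && length(raw$scenarios) == 1L &&
      grepl(",", raw$scenarios)) {
    raw$scenarios <- strsplit(raw$scenarios, ",[ ]*")[[1]]
  }
  do.call(study_config, raw)
}

#' Write a study configuration as a flat key:value file
#'
#' @param config A [study_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write cell summaries as delimited text
#'
#' Tab-separated machine output, one row per cell, full precision.
#'
#' @param results Data.frame from [run_study()] or [run_cell()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an implied covariance matrix as labeled delimited text
#'
#' @param cov An [implied_covariance()] matrix (or any labeled square
#'   matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_implied_covariance <- function(cov, path) {
  m <- unclass(cov)
  utils::write.table(data.frame(variable = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back cell summaries written by [write_study_results()]
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_study_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

fmt2 <- function(x) formatC(x, format = "f", digits = 2)

#' Render the published-style result tables
#'
#' Formats cell summaries the way the study reports them: coefficients and
#' SEs to two decimals, coverage as a whole percent, mean change scores
#' (change-score cells only) to two decimals. `table` selects one of the
#' six canonical layouts: 1 — appropriate MR at 50%/70% attrition; 2 —
#' appropriate change scores at 50%/70% (with Diff); 3/4 — inappropriate MR
#' / change scores at 50%; 5/6 — the negative-variant mirrors of 3/4.
#'
#' @param results Data.frame from [run_study()].
#' @param table Integer 1..6.
#' @return Character vector of formatted lines, invisibly printed with
#'   `cat`-able content.
#' @export
render_study_table <- function(results, table) {
  stopifnot(table %in% 1:6)
  sel <- switch(table,
    list(cause = "transient", method = "mr", sign = "positive",
         rates = c(0.5, 0.7), appropriate = TRUE,
         title = "Appropriate MR (transient population)"),
    list(cause = "enduring", method = "change_score", sign = "positive",
         rates = c(0.5, 0.7), appropriate = TRUE,
         title = "Appropriate change score (enduring population)"),
    list(cause = "enduring", method = "mr", sign = "positive",
         rates = 0.5, appropriate = FALSE,
         title = "Inappropriate MR (enduring population), 50% attrition"),
    list(cause = "transient", method = "change_score", sign = "positive",
         rates = 0.5, appropriate = FALSE,
         title = "Inappropriate change score (transient population), 50% attrition"),
    list(cause = "enduring", method = "mr", sign = "negative",
         rates = 0.5, appropriate = FALSE,
         title = "Inappropriate MR, negative variant, 50% attrition"),
    list(cause = "transient", method = "change_score", sign = "negative",
         rates = 0.5, appropriate = FALSE,
         title = "Inappropriate change score, negative variant, 50% attrition")
  )
  rows <- results[results$cause_type == sel$cause &
                    results$method == sel$method &
                    results$sign == sel$sign &
                    results$rate %in% sel$rates, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("results contain no cells for table ", table, call. = FALSE)
  }
  scen_order <- intersect(names(dropout_scenarios()), rows$scenario)
  scen_order <- c(scen_order, setdiff(unique(rows$scenario), scen_order))
  with_diff <- sel$method == "change_score"
  lines <- c(sel$title, strrep("-", nchar(sel$title)))
  for (rate in sel$rates) {
    if (length(sel$rates) > 1L) {
      lines <- c(lines, sprintf("%.0f%% attrition rate:", 100 * rate))
    }
    hdr <- sprintf("  %-12s %-12s %-10s %s", "scenario", "b_pred (SE)",
                   "coverage", if (with_diff) "Diff" else "")
    lines <- c(lines, sub(" +$", "", hdr))
    for (scen in scen_order) {
      r <- rows[rows$scenario == scen & rows$rate == rate, , drop = FALSE]
      if (nrow(r) == 0L) next
      lines <- c(lines, sub(" +$", "", sprintf(
        "  %-12s %-12s %-10s %s",
        scen,
        paste0(fmt2(r$mean_b), " (", fmt2(r$mean_se), ")"),
        paste0(round(r$coverage_pct), "%"),
        if (with_diff) fmt2(r$mean_diff) else ""
      )))
    }
  }
  lines
}

#' Write the run manifest
#'
#' Plain-text record of a completed run: the configuration echo, the
#' package version, timestamps, the seed-derivation scheme and every
#' output file produced.
#'
#' @param path Manifest path.
#' @param config The [study_config()] used.
#' @param files Named character vector of output files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, files) {
  manifest <- list(
    package = "rtmbias",
    version = as.character(utils::packageVersion("rtmbias")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    seed_scheme = paste(
      "replicate seed = (master_seed * 1000003 + stream * 10007 +",
      "replicate) mod (2^31 - 1); stream = 16 * population_code +",
      "scenario_index"),
    config = unclass(config),
    outputs = as.list(files)
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}
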