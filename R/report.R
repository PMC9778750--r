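# Report numbers are printed in scientific notation with 3 significant
# digits (the house style of risk tables); JSON keeps full precision.
fmt_sci <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 2, format = "e"))
}

#' Write a distribution-fit report
#'
#' Writes `fits.json` (machine-readable, full precision) and `fits.csv`
#' (3-significant-digit table) describing the three candidate fits and
#' the AIC selection.
#'
#' @param fits A `concentration_fits` object.
#' @param dir Output directory (created if needed).
#' @return The tidy fit table, invisibly.
#' @export
report_fit <- function(fits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- tidy(fits)
  write_fit_json(fits, file.path(dir, "fits.json"))
  human <- dplyr::mutate(tab, dplyr::across(
    c("param1", "param2", "log_likelihood", "aic"), fmt_sci))
  readr::write_csv(human, file.path(dir, "fits.csv"), progress = FALSE)
  invisible(tab)
}

#' Write per-age and lifetime risk tables
#'
#' Produces `cancer_risk_by_age.csv` (age, mean, percentile columns of
#' the cancer-risk term, with a lifetime ILCR footer row),
#' `hq_by_age.csv` (same shape for the hazard quotient) and
#' `assessment.json` with full-precision results plus run metadata (seed,
#' lognormal parameter convention, truncation resample count, package
#' version) so reruns are auditable. The JSON carries an explicit
#' `hq_below_1` flag.
#'
#' @param summary A `risk_summary` from [simulate_risk()].
#' @param dir Output directory.
#' @return `summary`, invisibly.
#' @export
report_assessment <- function(summary, dir) {
  if (!inherits(summary, "risk_summary")) {
    abort("`summary` must be a risk_summary.", class = "ricerisk_usage_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pn <- percentile_names(summary$config$percentiles)
  lt <- summary$lifetime

  risk_tab <- summary$per_group[c("label", "risk_mean", paste0("risk_", pn))]
  names(risk_tab) <- c("age", "mean", pn)
  ilcr_row <- lt[lt$metric == "ilcr", c("mean", pn)]
  risk_tab <- dplyr::bind_rows(risk_tab,
                               dplyr::mutate(ilcr_row, age = "ILCR"))
  hq_tab <- summary$per_group[c("label", "hq_mean", paste0("hq_", pn))]
  names(hq_tab) <- c("age", "mean", pn)
  hq_row <- lt[lt$metric == "hq", c("mean", pn)]
  hq_tab <- dplyr::bind_rows(hq_tab,
                             dplyr::mutate(hq_row, age = "Lifetime HQ"))

  for (x in list(list(risk_tab, "cancer_risk_by_age.csv"),
                 list(hq_tab, "hq_by_age.csv"))) {
    human <- dplyr::mutate(x[[1]],
                           dplyr::across(dplyr::where(is.numeric), fmt_sci))
    readr::write_csv(human, file.path(dir, x[[2]]), progress = FALSE)
  }

  g <- glance(summary)
  payload <- list(
    lifetime = lt,
    per_group = summary$per_group,
    hq_below_1 = g$hq_below_1,
    distribution = list(family = summary$dist$family,
                        params = as.list(summary$dist$params),
                        truncate_at_zero = summary$dist$truncate_at_zero),
    constants = unclass(summary$constants),
    config = unclass(summary$config),
    meta = summary$meta
  )
  jsonlite::write_json(payload, file.path(dir, "assessment.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Write a scenario comparison table
#'
#' One row per scenario: name, iAs limit, retained sample count, fitted
#' parameters, mean and 95th-percentile ILCR and percent reduction versus
#' baseline. Written as `scenarios.csv` (3-significant-digit) and
#' `scenarios.json` (full precision).
#'
#' @param results Tibble from [run_scenarios()].
#' @param dir Output directory.
#' @return `results`, invisibly.
#' @export
report_scenarios <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  human <- dplyr::mutate(results, dplyr::across(
    c("param1", "param2", "ilcr_mean", "ilcr_p95"), fmt_sci))
  readr::write_csv(human, file.path(dir, "scenarios.csv"), progress = FALSE)
  jsonlite::write_json(results, file.path(dir, "scenarios.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
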