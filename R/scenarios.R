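#' Define a mitigation scenario
#'
#' Three intervention kinds are supported, mirroring the common levers in
#' food-safety risk management:
#'
#' * `scenario_mcl()` — impose a maximum contaminant level: samples above
#'   the MCL are removed from the dataset, the concentration model is
#'   refit (family held to the baseline's selected family so small
#'   filtered datasets cannot flip family), and risk is re-simulated.
#' * `scenario_substitute()` — replace the concentration model outright,
#'   e.g. switching the supply to a low-iAs subgroup or variety whose
#'   fitted distribution is known.
#' * `scenario_exclude_ages()` — zero rice ingestion for young age bins
#'   (all bins with `age_start < max_excluded_age + 1`), leaving the
#'   table structure unchanged.
#'
#' @param name Scenario label used in reports.
#' @param mcl_ng_g Maximum contaminant level, ng/g (> 0).
#' @param replacement A [fitted_distribution()] to substitute.
#' @param max_excluded_age Ages `<= max_excluded_age` stop consuming rice.
#' @return An object of class `scenario`.
#' @export
scenario_mcl <- function(name, mcl_ng_g) {
  if (!is.numeric(mcl_ng_g) || length(mcl_ng_g) != 1L || mcl_ng_g <= 0) {
    abort("`mcl_ng_g` must be a single positive number.",
          class = "ricerisk_usage_error")
  }
  new_scenario(name, "mcl_filter", mcl_ng_g = mcl_ng_g)
}

#' @rdname scenario_mcl
#' @export
scenario_substitute <- function(name, replacement) {
  if (!inherits(replacement, "fitted_distribution")) {
    abort("`replacement` must be a fitted_distribution.",
          class = "ricerisk_usage_error")
  }
  new_scenario(name, "substitute_distribution", replacement = replacement)
}

#' @rdname scenario_mcl
#' @export
scenario_exclude_ages <- function(name, max_excluded_age) {
  if (!is.numeric(max_excluded_age) || length(max_excluded_age) != 1L ||
      max_excluded_age < 0) {
    abort("`max_excluded_age` must be a single non-negative age.",
          class = "ricerisk_usage_error")
  }
  new_scenario(name, "exclude_ages", max_excluded_age = max_excluded_age)
}

new_scenario <- function(name, kind, ...) {
  structure(list(name = name, kind = kind, ...), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  detail <- switch(x$kind,
    mcl_filter = sprintf("MCL %g ng/g", x$mcl_ng_g),
    substitute_distribution = sprintf("substitute %s model",
                                      x$replacement$family),
    exclude_ages = sprintf("no consumption <= %g years", x$max_excluded_age)
  )
  cat(sprintf("<scenario '%s': %s (%s)>\n", x$name, x$kind, detail))
  invisible(x)
}

#' Remove samples above a maximum contaminant level
#'
#' Retains samples with `ias_ng_g <= mcl_ng_g`; the input is not
#' modified. Removing every sample is an error (the scenario would have
#' no concentration data to refit).
#'
#' @param data A concentration tibble.
#' @param mcl_ng_g Threshold, ng/g (> 0).
#' @return The filtered tibble (`nrow()` gives the retained count).
#' @export
apply_mcl_filter <- function(data, mcl_ng_g) {
  if (!is.numeric(mcl_ng_g) || length(mcl_ng_g) != 1L || mcl_ng_g <= 0) {
    abort("`mcl_ng_g` must be a single positive number.",
          class = "ricerisk_usage_error")
  }
  if (!is.data.frame(data) || !"ias_ng_g" %in% names(data)) {
    abort("`data` must contain an `ias_ng_g` column.",
          class = "ricerisk_usage_error")
  }
  kept <- dplyr::filter(data, .data$ias_ng_g <= mcl_ng_g)
  if (nrow(kept) == 0) {
    abort(sprintf("MCL filter at %g ng/g removed every sample.", mcl_ng_g),
          class = "ricerisk_data_error")
  }
  kept
}

#' Zero rice ingestion for young age groups
#'
#' Sets `ingestion_rate_g_day` to 0 for every bin with
#' `age_start < max_excluded_age + 1` (so `max_excluded_age = 6` zeroes
#' the bins "<1" through "6"). The boundary is a documented convention;
#' the table structure is otherwise unchanged.
#'
#' @param table An exposure table.
#' @param max_excluded_age Age threshold, years.
#' @return The modified exposure table.
#' @export
exclude_ages <- function(table, max_excluded_age) {
  table <- as_exposure_table(table)
  dplyr::mutate(
    table,
    ingestion_rate_g_day = ifelse(.data$age_start < max_excluded_age + 1,
                                  0, .data$ingestion_rate_g_day)
  )
}

#' Evaluate a mitigation scenario against a baseline risk run
#'
#' Re-simulates risk under the intervention using the baseline's exposure
#' table, constants and Monte Carlo configuration (so the reduction
#' isolates the intervention), and reports the percent reduction in mean
#' lifetime ILCR, `100 * (1 - ILCR_scenario / ILCR_baseline)`.
#'
#' @param scenario A [scenario_mcl()], [scenario_substitute()] or
#'   [scenario_exclude_ages()] object.
#' @param baseline A `risk_summary` from [simulate_risk()]; it carries the
#'   distribution, table, constants and config the scenario reuses.
#' @param data The concentration dataset behind the baseline (required
#'   for MCL scenarios, which refilter and refit it).
#' @return An object of class `scenario_result` with the scenario echo,
#'   retained sample count, the distribution simulated, the scenario
#'   `risk_summary` and `reduction_pct`.
#' @examples
#' tbl <- generate_exposure_table()
#' base <- simulate_risk(fitted_distribution("normal", mean = 100.17, sd = 44.62),
#'                       tbl, config = simulation_config(5000, seed = 7))
#' half <- scenario_substitute("half", fitted_distribution(
#'   "normal", mean = 50.085, sd = 22.31))
#' run_scenario(half, base)$reduction_pct  # ~ 50%
#' @export
run_scenario <- function(scenario, baseline, data = NULL) {
  if (!inherits(scenario, "scenario")) {
    abort("`scenario` must be a scenario object.",
          class = "ricerisk_usage_error")
  }
  if (!inherits(baseline, "risk_summary")) {
    abort("`baseline` must be a risk_summary from simulate_risk().",
          class = "ricerisk_usage_error")
  }
  n_retained <- NA_integer_
  table <- baseline$table
  dist <- baseline$dist

  if (scenario$kind == "mcl_filter") {
    if (is.null(data)) {
      abort("MCL scenarios need the baseline concentration dataset.",
            class = "ricerisk_usage_error")
    }
    kept <- apply_mcl_filter(data, scenario$mcl_ng_g)
    n_retained <- nrow(kept)
    refit <- fit_concentration(kept$ias_ng_g,
                               truncate_at_zero = dist$truncate_at_zero)
    dist <- refit[[baseline$dist$family]]
  } else if (scenario$kind == "substitute_distribution") {
    dist <- scenario$replacement
  } else if (scenario$kind == "exclude_ages") {
    table <- exclude_ages(table, scenario$max_excluded_age)
  }

  summary <- simulate_risk(dist, table, baseline$constants, baseline$config)
  base_ilcr <- lifetime_stat(baseline, "ilcr")
  scen_ilcr <- lifetime_stat(summary, "ilcr")
  reduction <- if (base_ilcr == 0) 0 else 100 * (1 - scen_ilcr / base_ilcr)

  structure(
    list(scenario = scenario, n_retained = n_retained, dist = dist,
         summary = summary, reduction_pct = reduction),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result '%s': mean ILCR %.3e, reduction %.2f%%>\n",
              x$scenario$name, lifetime_stat(x$summary, "ilcr"),
              x$reduction_pct))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scenario_result <- function(x, ...) {
  lt <- x$summary$lifetime
  ilcr <- lt[lt$metric == "ilcr", ]
  pn <- percentile_names(x$summary$config$percentiles)
  p95 <- if ("p95" %in% pn) ilcr$p95 else NA_real_
  tibble::tibble(
    scenario = x$scenario$name,
    kind = x$scenario$kind,
    ias_limit_ng_g = if (x$scenario$kind == "mcl_filter")
      x$scenario$mcl_ng_g else NA_real_,
    n_retained = x$n_retained,
    family = x$dist$family,
    param1 = unname(x$dist$params[1]),
    param2 = if (length(x$dist$params) > 1)
      unname(x$dist$params[2]) else NA_real_,
    ilcr_mean = ilcr$mean,
    ilcr_p95 = p95,
    reduction_pct = x$reduction_pct
  )
}

#' Evaluate a list of scenarios into one report table
#'
#' @param scenarios List of `scenario` objects.
#' @param baseline Baseline `risk_summary`.
#' @param data Concentration dataset (needed by MCL scenarios).
#' @return A tibble with one row per scenario: name, kind, iAs limit,
#'   retained n, fitted parameters, mean and 95th-percentile ILCR, and
#'   percent reduction versus baseline.
#' @export
run_scenarios <- function(scenarios, baseline, data = NULL) {
  purrr::map_dfr(scenarios, function(s) tidy(run_scenario(s, baseline, data)))
}
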