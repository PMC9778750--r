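#' Monte Carlo configuration
#'
#' @param iterations Number of Monte Carlo iterations, default 100000.
#' @param seed Optional integer seed; recorded in every output.
#' @param percentiles Percentiles (in (0, 100)) reported alongside means,
#'   default `c(50, 95)`.
#' @param ci_level Confidence level echoed in metadata, default 0.95.
#' @param param_convention Lognormal parameter reading, see
#'   [sample_concentrations()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(iterations = 100000, seed = NULL,
                              percentiles = c(50, 95), ci_level = 0.95,
                              param_convention = c("log_scale", "arithmetic")) {
  param_convention <- match.arg(param_convention)
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1) {
    abort("`iterations` must be >= 1.", class = "ricerisk_usage_error")
  }
  if (any(percentiles <= 0 | percentiles >= 100)) {
    abort("`percentiles` must lie strictly between 0 and 100.",
          class = "ricerisk_usage_error")
  }
  structure(
    list(iterations = as.integer(iterations), seed = seed,
         percentiles = percentiles, ci_level = ci_level,
         param_convention = param_convention),
    class = "simulation_config"
  )
}

percentile_names <- function(percentiles) sprintf("p%g", percentiles)

#' Summarise Monte Carlo draws
#'
#' Empirical percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), so results are reproducible bit-exactly
#' given a seed. The Monte Carlo standard error is `sd/sqrt(n)`.
#'
#' @param draws Non-empty numeric vector of per-iteration values.
#' @param percentiles Percentiles in (0, 100).
#' @return A one-row tibble: `mean`, one `p<q>` column per requested
#'   percentile, `mc_se`.
#' @examples
#' summarize_draws(1:100)  # p95 = 95.05 by interpolation
#' @export
summarize_draws <- function(draws, percentiles = c(50, 95)) {
  if (length(draws) == 0) {
    abort("`draws` must be non-empty.", class = "ricerisk_usage_error")
  }
  qs <- quantile(draws, probs = percentiles / 100, names = FALSE, type = 7)
  out <- tibble::tibble(mean = mean(draws))
  out[percentile_names(percentiles)] <- as.list(qs)
  out$mc_se <- stats::sd(draws) / sqrt(length(draws))
  out
}

#' Propagate concentration uncertainty through the risk equations
#'
#' For each iteration one concentration draw is applied to all age groups:
#' an iteration represents a lifetime lived under one long-run mean
#' concentration, so age-group terms are fully correlated within an
#' iteration. This choice affects percentiles but not means (the risk
#' equations are linear in concentration). Exposure factors are fixed
#' constants per age group. Per-iteration lifetime ILCR and HQ are
#' within-iteration sums over groups; summaries are taken over
#' iterations. The same draws feed the cancer and HQ sides, so the
#' identity `ILCR == HQ * SF * RfD` holds on means to machine precision.
#'
#' @param dist A [fitted_distribution()] (the concentration model).
#' @param table An exposure table, see [as_exposure_table()].
#' @param constants A [risk_constants()] object.
#' @param config A [simulation_config()].
#' @return An object of class `risk_summary` with elements `per_group`
#'   (tibble: label, mean and percentiles of the cancer-risk and HQ
#'   terms), `lifetime` (tibble: one row per metric `ilcr`, `hq`), and
#'   metadata (`dist`, `table`, `constants`, `config`, `meta`). Use
#'   [tidy()] / [glance()] to extract tables.
#' @examples
#' tbl <- generate_exposure_table()
#' dist <- fitted_distribution("normal", mean = 100.17, sd = 44.62)
#' rs <- simulate_risk(dist, tbl, config = simulation_config(2000, seed = 1))
#' glance(rs)
#' @export
simulate_risk <- function(dist, table, constants = risk_constants(),
                          config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be a simulation_config().",
          class = "ricerisk_usage_error")
  }
  table <- as_exposure_table(table, lifetime_years = constants$lifetime_years)

  draws <- sample_concentrations(
    dist, config$iterations,
    seed = if (is.null(config$seed)) NULL else child_seed(config$seed, 1L),
    param_convention = config$param_convention
  )
  resamples <- attr(draws, "truncation_resamples") %||% 0L

  # Risk is linear in concentration: per-group term_ij = k_j * C_i.
  unit_terms <- age_risk_terms(table, 1, constants)
  k_risk <- unit_terms$cancer_risk
  k_hq <- unit_terms$hq

  pn <- percentile_names(config$percentiles)
  per_group <- purrr::map_dfr(seq_len(nrow(table)), function(j) {
    risk_s <- summarize_draws(k_risk[j] * draws, config$percentiles)
    hq_s <- summarize_draws(k_hq[j] * draws, config$percentiles)
    row <- tibble::tibble(label = table$label[j],
                          risk_mean = risk_s$mean)
    row[paste0("risk_", pn)] <- risk_s[pn]
    row$hq_mean <- hq_s$mean
    row[paste0("hq_", pn)] <- hq_s[pn]
    row
  })

  ilcr_draws <- sum(k_risk) * draws
  hq_draws <- sum(k_hq) * draws
  lifetime <- dplyr::bind_rows(
    dplyr::mutate(summarize_draws(ilcr_draws, config$percentiles),
                  metric = "ilcr", .before = 1),
    dplyr::mutate(summarize_draws(hq_draws, config$percentiles),
                  metric = "hq", .before = 1)
  )

  structure(
    list(
      per_group = per_group,
      lifetime = lifetime,
      dist = dist,
      table = table,
      constants = constants,
      config = config,
      meta = list(
        truncation_resamples = resamples,
        concentration_mean = mean(draws),
        package_version = as.character(utils::packageVersion("ricerisk"))
      )
    ),
    class = "risk_summary"
  )
}

#' @export
print.risk_summary <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<risk_summary: %s concentration model, %d iterations>\n",
              x$dist$family, x$config$iterations))
  cat(sprintf("  lifetime ILCR: mean %.3e, p95 %.3e\n",
              g$ilcr_mean, g$ilcr_p95))
  cat(sprintf("  lifetime HQ:   mean %.3e, p95 %.3e%s\n",
              g$hq_mean, g$hq_p95,
              if (g$hq_mean < 1) "  (below 1)" else "  (ABOVE 1)"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.risk_summary <- function(x, ...) x$per_group

#' @exportS3Method generics::glance
glance.risk_summary <- function(x, ...) {
  lt <- x$lifetime
  ilcr <- lt[lt$metric == "ilcr", ]
  hq <- lt[lt$metric == "hq", ]
  out <- tibble::tibble(
    ilcr_mean = ilcr$mean,
    hq_mean = hq$mean,
    iterations = x$config$iterations,
    seed = x$config$seed %||% NA_integer_,
    param_convention = x$config$param_convention,
    hq_below_1 = hq$mean < 1
  )
  for (pn in percentile_names(x$config$percentiles)) {
    out[[paste0("ilcr_", pn)]] <- ilcr[[pn]]
    out[[paste0("hq_", pn)]] <- hq[[pn]]
  }
  out
}

lifetime_stat <- function(summary, metric, col = "mean") {
  lt <- summary$lifetime
  lt[[col]][lt$metric == metric]
}
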