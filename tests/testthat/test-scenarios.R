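baseline_run <- function(tbl = generate_exposure_table(), iterations = 20000,
                         seed = 55) {
  simulate_risk(white_dist(), tbl,
                config = simulation_config(iterations, seed = seed))
}

test_that("the MCL filter retains exactly the samples at or below the limit", {
  ds <- tibble::tibble(ias_ng_g = c(10, 60, 120, 250))
  kept <- apply_mcl_filter(ds, 100)
  expect_equal(kept$ias_ng_g, c(10, 60))
  expect_equal(nrow(apply_mcl_filter(ds, Inf)), 4)
  expect_identical(apply_mcl_filter(kept, 100), kept) # idempotent
  expect_error(apply_mcl_filter(ds, 5), class = "ricerisk_data_error")
  expect_error(apply_mcl_filter(ds, -1), class = "ricerisk_usage_error")
  expect_equal(ds$ias_ng_g, c(10, 60, 120, 250)) # input untouched
})

test_that("MCL-100 retention on synthetic white rice matches the normal CDF", {
  ds <- generate_concentration_data(seed = 909)
  white <- dplyr::filter(ds, rice_type == "white")
  kept <- apply_mcl_filter(white, 100)
  p <- (pnorm(100, 100.17, 44.62) - pnorm(0, 100.17, 44.62)) /
    (1 - pnorm(0, 100.17, 44.62))
  lo <- qbinom(0.005, 64, p)
  hi <- qbinom(0.995, 64, p)
  expect_gte(nrow(kept), lo)
  expect_lte(nrow(kept), hi)
})

test_that("age exclusion zeroes the right bins at each boundary", {
  tbl <- generate_exposure_table()
  ex0 <- exclude_ages(tbl, 0)
  expect_equal(ex0$ingestion_rate_g_day[ex0$label == "<1"], 0)
  expect_true(all(ex0$ingestion_rate_g_day[ex0$label != "<1"] > 0))

  ex6 <- exclude_ages(tbl, 6)
  zeroed <- ex6$label[ex6$ingestion_rate_g_day == 0]
  expect_setequal(zeroed, c("<1", as.character(1:6)))

  ex70 <- exclude_ages(tbl, 70)
  expect_true(all(ex70$ingestion_rate_g_day == 0))
  expect_equal(closed_form_ilcr(ex70, 100)$ilcr, 0)
})

test_that("an identity scenario yields zero reduction", {
  base <- baseline_run()
  same <- run_scenario(scenario_substitute("same", white_dist()), base)
  expect_equal(same$reduction_pct, 0)
})

test_that("halving the (untruncated) mean halves the mean ILCR", {
  tbl <- toy_table()
  d_full <- fitted_distribution("normal", mean = 100, sd = 20,
                                truncate_at_zero = FALSE)
  d_half <- fitted_distribution("normal", mean = 50, sd = 10,
                                truncate_at_zero = FALSE)
  base <- simulate_risk(d_full, tbl,
                        config = simulation_config(20000, seed = 3))
  res <- run_scenario(scenario_substitute("half", d_half), base)
  expect_equal(res$reduction_pct, 50, tolerance = 1e-10) # shared seed, exact
})

test_that("substitution reductions are invariant to the exposure table", {
  scen <- scenario_substitute(
    "mcl50", fitted_distribution("normal", mean = 30.55, sd = 16.85))
  reductions <- vapply(c(1, 2), function(s) {
    base <- baseline_run(as_exposure_table(random_table(s)))
    run_scenario(scen, base)$reduction_pct
  }, numeric(1))
  se_pct <- 100 * 6 * (44.62 / sqrt(20000)) / 101.6
  expect_lt(abs(reductions[1] - reductions[2]), se_pct)
})

test_that("lower MCLs give monotonically larger reductions", {
  ds <- generate_concentration_data(seed = 31)
  white <- dplyr::filter(ds, rice_type == "white")
  base <- baseline_run()
  reds <- vapply(c(150, 100, 75, 50), function(mcl) {
    run_scenario(scenario_mcl(paste(mcl), mcl), base, white)$reduction_pct
  }, numeric(1))
  expect_true(all(diff(reds) > 0))
})

test_that("MCL scenarios refit within the baseline's selected family", {
  ds <- generate_concentration_data(seed = 12)
  white <- dplyr::filter(ds, rice_type == "white")
  base <- baseline_run()
  res <- run_scenario(scenario_mcl("mcl100", 100), base, white)
  expect_equal(res$dist$family, "normal")
  expect_equal(res$n_retained, sum(white$ias_ng_g <= 100))
  expect_error(run_scenario(scenario_mcl("m", 100), base),
               class = "ricerisk_usage_error") # dataset required
})

test_that("age-exclusion reduction equals the zeroed bins' share of risk", {
  base <- baseline_run()
  res <- run_scenario(scenario_exclude_ages("no young", 6), base)
  zeroed <- base$table$age_start < 7
  share <- 100 * sum(base$per_group$risk_mean[zeroed]) /
    sum(base$per_group$risk_mean)
  # shared seed means identical draws, so the identity is exact
  expect_equal(res$reduction_pct, share, tolerance = 1e-9)
})

test_that("scenario batches produce a well-formed comparison table", {
  ds <- generate_concentration_data(seed = 47)
  white <- dplyr::filter(ds, rice_type == "white")
  base <- baseline_run(iterations = 5000)
  scens <- list(
    scenario_mcl("MCL 100", 100),
    scenario_substitute("Puita supply", fitted_distribution(
      "lognormal", mu = 3.51, sigma = 0.91)),
    scenario_exclude_ages("No rice <= 6 y", 6)
  )
  out <- run_scenarios(scens, base, white)
  expect_equal(nrow(out), 3)
  expect_equal(out$scenario, c("MCL 100", "Puita supply", "No rice <= 6 y"))
  expect_true(all(out$reduction_pct <= 100))
  expect_equal(out$ias_limit_ng_g[1], 100)
  expect_true(is.na(out$ias_limit_ng_g[3]))
})
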