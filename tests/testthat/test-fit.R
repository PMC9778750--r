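test_that("closed-form MLEs match hand arithmetic and the AIC definition", {
  vals <- c(1, 2, 3)
  fits <- fit_concentration(vals)
  expect_equal(fits$normal$params[["mean"]], 2)
  expect_equal(fits$normal$params[["sd"]], sqrt(2 / 3))

  set.seed(1)
  v50 <- rexp(200, 1 / 50)
  v50 <- v50 * 50 / mean(v50) # force sample mean exactly 50
  f <- fit_concentration(v50)
  expect_equal(f$exponential$params[["rate"]], 0.02)

  for (fam in c("normal", "lognormal", "exponential")) {
    k <- if (fam == "exponential") 1 else 2
    expect_identical(fits[[fam]]$aic, 2 * k - 2 * fits[[fam]]$log_likelihood)
  }
})

test_that("fits agree with an independent MLE implementation", {
  skip_if_not_installed("fitdistrplus")
  set.seed(42)
  x <- rlnorm(200, 4, 0.7)
  ours <- fit_concentration(x)

  ref_n <- fitdistrplus::fitdist(x, "norm")
  expect_equal(ours$normal$params[["mean"]], unname(ref_n$estimate["mean"]),
               tolerance = 1e-4)
  expect_equal(ours$normal$params[["sd"]], unname(ref_n$estimate["sd"]),
               tolerance = 1e-3)
  expect_equal(ours$normal$aic, ref_n$aic, tolerance = 1e-4)

  ref_l <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(ours$lognormal$params[["mu"]],
               unname(ref_l$estimate["meanlog"]), tolerance = 1e-4)
  expect_equal(ours$lognormal$params[["sigma"]],
               unname(ref_l$estimate["sdlog"]), tolerance = 1e-3)

  ref_e <- fitdistrplus::fitdist(x, "exp")
  expect_equal(ours$exponential$params[["rate"]],
               unname(ref_e$estimate["rate"]), tolerance = 1e-3)
  expect_equal(ours$exponential$aic, ref_e$aic, tolerance = 1e-3)
})

test_that("lognormal fit excludes non-positive values with a message", {
  vals <- c(0, 10, 20, 30)
  expect_message(fits <- fit_concentration(vals), "non-positive")
  expect_equal(fits$n_lognormal_excluded, 1)
  expect_equal(fits$lognormal$n, 3)
  expect_equal(fits$normal$n, 4) # normal/exponential keep all values
  expect_error(fit_concentration(7), class = "ricerisk_data_error")
})

test_that("parameter recovery: refitting draws from a fitted model", {
  x <- sample_concentrations(brown_dist(), 5000, seed = 9)
  f <- fit_concentration(x)$lognormal
  expect_lt(abs(f$params[["mu"]] - 4.1) / 4.1, 0.05)
  expect_lt(abs(f$params[["sigma"]] - 0.9) / 0.9, 0.05)
})

test_that("AIC selection recovers the generating family across replicates", {
  lognormal_wins <- 0
  for (i in 1:200) {
    x <- sample_concentrations(brown_dist(), 90, seed = 5000 + i)
    if (select_best(fit_concentration(x))$family == "lognormal") {
      lognormal_wins <- lognormal_wins + 1
    }
  }
  expect_gte(lognormal_wins, 180)

  normal_wins <- 0
  for (i in 1:200) {
    x <- sample_concentrations(white_dist(), 64, seed = 7000 + i)
    if (select_best(fit_concentration(x))$family == "normal") {
      normal_wins <- normal_wins + 1
    }
  }
  expect_gte(normal_wins, 160)
})

test_that("selection takes the minimum AIC with a deterministic tie-break", {
  mk <- function(fam, aic) {
    f <- switch(fam,
      normal = fitted_distribution("normal", mean = 0, sd = 1),
      lognormal = fitted_distribution("lognormal", mu = 0, sigma = 1),
      exponential = fitted_distribution("exponential", rate = 1))
    f$aic <- aic
    f
  }
  fits <- list(mk("normal", 10), mk("lognormal", 12), mk("exponential", 14))
  expect_equal(select_best(fits)$family, "normal")
  fits <- list(mk("normal", 12), mk("lognormal", 12), mk("exponential", 12))
  expect_equal(select_best(fits)$family, "normal") # fixed family order
  fits <- list(mk("exponential", 5), mk("lognormal", 5))
  expect_equal(select_best(fits)$family, "lognormal")
  expect_error(select_best(list()), class = "ricerisk_usage_error")
})

test_that("sampling honours truncation, conventions and degenerate scales", {
  x <- sample_concentrations(
    fitted_distribution("normal", mean = 30.55, sd = 16.85), 20000, seed = 3)
  expect_true(all(x >= 0))
  expect_gt(attr(x, "truncation_resamples"), 0) # ~3.5% negative mass hit

  degen <- fitted_distribution("normal", mean = 80, sd = 0)
  expect_equal(sample_concentrations(degen, 10, seed = 1),
               rep(80, 10), ignore_attr = TRUE)

  # log-scale convention: mean converges to exp(mu + sigma^2/2)
  y <- sample_concentrations(brown_dist(), 100000, seed = 4)
  m <- exp(4.1 + 0.9^2 / 2)
  s <- m * sqrt(exp(0.9^2) - 1)
  expect_lt(abs(mean(y) - m), 3 * s / sqrt(1e5))

  # arithmetic convention: mean converges to mu itself
  z <- sample_concentrations(brown_dist(), 100000, seed = 4,
                             param_convention = "arithmetic")
  expect_lt(abs(mean(z) - 4.1), 3 * 0.9 / sqrt(1e5))

  expect_error(sample_concentrations(brown_dist(), 0),
               class = "ricerisk_usage_error")
})

test_that("closed-form means agree with numerical integration", {
  expect_equal(distribution_mean(fitted_distribution("exponential",
                                                     rate = 0.02)), 50)
  expect_equal(distribution_mean(brown_dist()), exp(4.1 + 0.405),
               tolerance = 1e-12)
  for (p in list(c(100.17, 44.62), c(30.55, 16.85), c(71.94, 22.47))) {
    d <- fitted_distribution("normal", mean = p[1], sd = p[2])
    expect_equal(distribution_mean(d), truncnorm_mean_numeric(p[1], p[2]),
                 tolerance = 1e-8)
  }
  untrunc <- fitted_distribution("normal", mean = 100.17, sd = 44.62,
                                 truncate_at_zero = FALSE)
  expect_equal(distribution_mean(untrunc), 100.17)
})

test_that("empirical truncated-normal mean matches the closed form", {
  d <- fitted_distribution("normal", mean = 100.17, sd = 44.62)
  x <- sample_concentrations(d, 100000, seed = 8)
  expect_lt(abs(mean(x) - distribution_mean(d)), 3 * 44.6 / sqrt(1e5))
})
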