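# Shared fixtures, built in code at test time.

# One age bin covering the whole lifetime; the simplest exposure table.
single_group_table <- function(ir = 167, bw = 60, ef = 312.85,
                               age_start = 0, age_end = 70) {
  as_exposure_table(tibble::tibble(
    label = "all",
    age_start = age_start,
    age_end = age_end,
    exposure_duration = age_end - age_start,
    ingestion_rate_g_day = ir,
    body_weight_kg = bw,
    exposure_frequency_d_yr = ef
  ))
}

# A small contiguous multi-bin table with heterogeneous factors.
toy_table <- function(ef = 312.85) {
  as_exposure_table(tibble::tibble(
    label = c("child", "teen", "adult"),
    age_start = c(0, 10, 20),
    age_end = c(10, 20, 70),
    exposure_duration = c(10, 10, 50),
    ingestion_rate_g_day = c(80, 120, 167),
    body_weight_kg = c(20, 45, 60),
    exposure_frequency_d_yr = ef
  ))
}

# A random (but valid) exposure table, for table-invariance properties.
random_table <- function(seed) {
  set.seed(seed)
  edges <- sort(c(0, runif(4, 1, 69), 70))
  tibble::tibble(
    label = paste0("g", seq_len(5)),
    age_start = edges[-6],
    age_end = edges[-1],
    exposure_duration = diff(edges),
    ingestion_rate_g_day = runif(5, 20, 250),
    body_weight_kg = runif(5, 10, 80),
    exposure_frequency_d_yr = runif(5, 100, 365)
  )
}

# Zero-truncated normal mean by numerical integration (independent of the
# closed form used in the package).
truncnorm_mean_numeric <- function(m, s) {
  num <- stats::integrate(function(x) x * stats::dnorm(x, m, s), 0, Inf,
                          rel.tol = 1e-10)$value
  num / (1 - stats::pnorm(0, m, s))
}

white_dist <- function(truncate = TRUE) {
  fitted_distribution("normal", mean = 100.17, sd = 44.62,
                      truncate_at_zero = truncate)
}

brown_dist <- function() {
  fitted_distribution("lognormal", mu = 4.1, sigma = 0.9)
}
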