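# Moment-matched lognormal: log-scale (mu, sigma) reproducing an
# arithmetic mean m and sd s. Degenerate s = 0 gives a point mass at m.
lnorm_from_moments <- function(m, s) {
  if (m <= 0) {
    abort("Lognormal moment matching needs a positive mean.",
          class = "ricerisk_usage_error")
  }
  sdlog2 <- log(1 + (s / m)^2)
  c(mu = log(m) - sdlog2 / 2, sigma = sqrt(sdlog2))
}

#' Default stratum specification for the synthetic concentration dataset
#'
#' One row per sampling stratum: 64 white market samples from a
#' zero-truncated Normal(100.17, 44.62) ng/g, and 90 brown samples split
#' into 69 farm (19 of the Irga 424 variety at 80.7 +/- 22.35, 48 Puita
#' at 46.58 +/- 31.68, 2 unclassified at the pooled farm 57.36 +/- 34.36)
#' and 21 market samples at 154.91 +/- 44.8, each drawn from a lognormal
#' moment-matched to the stratum mean/sd (brown concentrations are
#' right-skewed and lognormal-selected when pooled).
#'
#' @return A tibble with columns `rice_type`, `origin`, `variety`, `n`,
#'   `family`, `mean`, `sd`.
#' @export
default_dataset_spec <- function() {
  tibble::tribble(
    ~rice_type, ~origin,  ~variety,   ~n, ~family,     ~mean,  ~sd,
    "white",    "market", NA,         64L, "normal",    100.17, 44.62,
    "brown",    "farm",   "Irga 424", 19L, "lognormal", 80.7,   22.35,
    "brown",    "farm",   "Puita",    48L, "lognormal", 46.58,  31.68,
    "brown",    "farm",   NA,          2L, "lognormal", 57.36,  34.36,
    "brown",    "market", NA,         21L, "lognormal", 154.91, 44.8
  )
}

#' Generate a synthetic iAs concentration dataset
#'
#' Draws samples stratum-by-stratum from `spec` with metadata attached,
#' deterministically given `seed` (each stratum reseeds from a derived
#' child seed, so stratum order or extra strata never perturb earlier
#' draws). Normal strata are sampled with rejection at zero; lognormal
#' strata are moment-matched to the stratum mean/sd. Farm samples also
#' receive a cadmium concentration weakly correlated with iAs
#' (target r = 0.049 on the latent normal scale; Cd marginal 10 +/- 5
#' ng/g, a fixture choice), so the As-Cd correlation analysis is
#' exercisable end to end.
#'
#' @param spec Stratum table, see [default_dataset_spec()].
#' @param seed Optional integer seed.
#' @param cd_target_r Latent correlation between iAs and Cd in farm
#'   strata.
#' @return A concentration tibble (columns as in
#'   [read_concentration_data()]).
#' @export
generate_concentration_data <- function(spec = default_dataset_spec(),
                                        seed = NULL, cd_target_r = 0.049) {
  if (!is.data.frame(spec) ||
      !all(c("rice_type", "n", "family", "mean", "sd") %in% names(spec))) {
    abort("`spec` must have rice_type, n, family, mean, sd columns.",
          class = "ricerisk_usage_error")
  }
  if (any(spec$n < 1)) {
    abort("Every stratum needs n >= 1.", class = "ricerisk_usage_error")
  }
  strata <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    row <- spec[i, ]
    stratum_seed <- if (is.null(seed)) NULL else child_seed(seed, 10L + i)
    with_seed(stratum_seed, {
      x <- switch(row$family,
        normal = {
          v <- rnorm(row$n, row$mean, row$sd)
          while (any(neg <- v < 0)) {
            v[neg] <- rnorm(sum(neg), row$mean, row$sd)
          }
          v
        },
        lognormal = {
          p <- lnorm_from_moments(row$mean, row$sd)
          if (p[["sigma"]] == 0) rep(row$mean, row$n)
          else rlnorm(row$n, p[["mu"]], p[["sigma"]])
        },
        abort(sprintf("Unsupported stratum family: %s", row$family),
              class = "ricerisk_usage_error")
      )
      origin <- if ("origin" %in% names(row)) row$origin else NA_character_
      if (is.na(origin)) origin <- "unknown"
      cd <- rep(NA_real_, row$n)
      if (identical(origin, "farm") && row$n >= 2 && stats::sd(x) > 0) {
        z_as <- (x - mean(x)) / stats::sd(x)
        z_noise <- rnorm(row$n)
        cd <- pmax(0, 10 + 5 * (cd_target_r * z_as +
                                  sqrt(1 - cd_target_r^2) * z_noise))
      }
      tibble::tibble(
        sample_id = sprintf("S%02d_%03d", i, seq_len(row$n)),
        rice_type = row$rice_type,
        origin = origin,
        city = NA_character_,
        state = NA_character_,
        variety = if ("variety" %in% names(row))
          rep(row$variety, row$n) else NA_character_,
        ias_ng_g = x,
        cd_ng_g = cd
      )
    })
  })
  strata
}

#' Generate an age-stratified exposure-factor table
#'
#' Builds the 27-bin age structure used throughout the risk assessment:
#' "<1" (rice consumption starting at 4 months, so ED = 8/12 year),
#' yearly bins 1-19, then 5- or 10-year adult bins up to 70
#' (total ED = 69.67 years). Body weight follows a piecewise-linear
#' growth curve through fixture anchors (about 8 kg in infancy rising to
#' a 60 kg adult plateau with a mild decline after 65). Ingestion rates
#' give every adult bin (age 20+) `adult_ir` g raw rice/day and scale a
#' monotone child profile so the ED-weighted all-age mean equals
#' `all_age_mean_ir` exactly. Exposure frequency is constant, default
#' 6/7 of the year (rice eaten six days a week).
#'
#' @param adult_ir Adult ingestion rate, g raw rice/day. Default 167.
#' @param all_age_mean_ir Target ED-weighted mean ingestion rate across
#'   all ages, g/day. Default 156.6.
#' @param exposure_frequency Days/year of rice consumption, default
#'   `365 * 6 / 7` (= 312.857...).
#' @return A validated `exposure_table` tibble with 27 rows.
#' @export
generate_exposure_table <- function(adult_ir = 167,
                                    all_age_mean_ir = 156.6,
                                    exposure_frequency = 365 * 6 / 7) {
  if (adult_ir < all_age_mean_ir) {
    abort(paste0("Infeasible targets: the adult rate must be at least the ",
                 "all-age mean (children cannot make up the difference)."),
          class = "ricerisk_usage_error")
  }
  age_start <- c(1 / 3, 1:19, 20, 25, 30, 35, 45, 55, 65)
  age_end <- c(1, 2:20, 25, 30, 35, 45, 55, 65, 70)
  label <- c("<1", as.character(1:19),
             "20 to <25", "25 to <30", "30 to <35",
             "35 to <45", "45 to <55", "55 to <65", "65 to <70")
  ed <- age_end - age_start
  mid <- (age_start + age_end) / 2

  # Fixture growth-curve anchors (kg), not survey claims.
  bw_anchor_age <- c(0.5, 1, 5, 10, 15, 20, 65, 70)
  bw_anchor_kg <- c(8, 10, 18, 33, 53, 60, 60, 57)
  bw <- stats::approx(bw_anchor_age, bw_anchor_kg, xout = mid, rule = 2)$y

  adult <- age_start >= 20
  # Child intake shape: modest in infancy, rising through adolescence;
  # only the shape matters, the level is pinned by the all-age mean.
  child_base <- ifelse(age_start < 1, 40, 60 + 5.5 * age_start)[!adult]
  target_total <- all_age_mean_ir * sum(ed)
  child_scale <- (target_total - adult_ir * sum(ed[adult])) /
    sum(ed[!adult] * child_base)
  if (child_scale <= 0) {
    abort("Infeasible targets: implied child intake is non-positive.",
          class = "ricerisk_usage_error")
  }
  ir <- numeric(length(ed))
  ir[adult] <- adult_ir
  ir[!adult] <- child_scale * child_base

  as_exposure_table(tibble::tibble(
    label = label,
    age_start = age_start,
    age_end = age_end,
    exposure_duration = ed,
    ingestion_rate_g_day = ir,
    body_weight_kg = bw,
    exposure_frequency_d_yr = exposure_frequency
  ))
}

#' Generate As-Cd concentration pairs with a target correlation
#'
#' Draws from a bivariate normal with the requested correlation between
#' the latent variables, rejecting pairs with a negative component so
#' both concentrations stay physical.
#'
#' @param n Number of pairs, >= 3.
#' @param target_r Target Pearson correlation, |r| < 1. Default 0.049
#'   (the near-null As-Cd association in farm brown rice).
#' @param mean_as,sd_as iAs marginal, ng/g. Defaults 57.36 / 34.36.
#' @param mean_cd,sd_cd Cd marginal, ng/g (fixture constants 10 / 5).
#' @param seed Optional integer seed.
#' @return A tibble with columns `ias_ng_g`, `cd_ng_g`.
#' @export
generate_as_cd_pairs <- function(n, target_r = 0.049,
                                 mean_as = 57.36, sd_as = 34.36,
                                 mean_cd = 10, sd_cd = 5, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 3) {
    abort("`n` must be at least 3.", class = "ricerisk_usage_error")
  }
  if (!is.numeric(target_r) || abs(target_r) >= 1) {
    abort("`target_r` must satisfy |r| < 1.",
          class = "ricerisk_usage_error")
  }
  with_seed(seed, {
    draw_pairs <- function(k) {
      z1 <- rnorm(k)
      z2 <- target_r * z1 + sqrt(1 - target_r^2) * rnorm(k)
      cbind(mean_as + sd_as * z1, mean_cd + sd_cd * z2)
    }
    xy <- draw_pairs(n)
    while (any(neg <- xy[, 1] < 0 | xy[, 2] < 0)) {
      xy[neg, ] <- draw_pairs(sum(neg))
    }
    tibble::tibble(ias_ng_g = xy[, 1], cd_ng_g = xy[, 2])
  })
}
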