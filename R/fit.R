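fit_families <- c("normal", "lognormal", "exponential")

#' Construct a parametric concentration distribution
#'
#' The sampling source for the Monte Carlo engine. Parameters by family:
#' `normal` — `mean`, `sd` (ng/g); `lognormal` — `mu`, `sigma`, by default
#' the mean and sd of log concentration (see `param_convention` in
#' [sample_concentrations()]); `exponential` — `rate` (per ng/g).
#'
#' @param family One of `"normal"`, `"lognormal"`, `"exponential"`.
#' @param ... Named numeric parameters for the family.
#' @param n Sample size behind the fit, if any.
#' @param log_likelihood,aic Fit statistics, if any. When omitted but
#'   derivable they are left `NA`.
#' @param truncate_at_zero Logical; if `TRUE` (default) sampling rejects
#'   negative draws so concentrations stay physical. Only the normal
#'   family can produce negative mass.
#' @return An object of class `fitted_distribution`.
#' @examples
#' fitted_distribution("normal", mean = 100.17, sd = 44.62)
#' fitted_distribution("lognormal", mu = 4.1, sigma = 0.9)
#' @export
fitted_distribution <- function(family, ..., n = NA_integer_,
                                log_likelihood = NA_real_, aic = NA_real_,
                                truncate_at_zero = TRUE) {
  family <- match.arg(family, fit_families)
  params <- c(...)
  expected <- switch(family,
    normal = c("mean", "sd"),
    lognormal = c("mu", "sigma"),
    exponential = "rate"
  )
  if (!setequal(names(params), expected)) {
    abort(sprintf("Family '%s' needs parameters: %s.", family,
                  paste(expected, collapse = ", ")),
          class = "ricerisk_usage_error")
  }
  params <- params[expected]
  scale_par <- switch(family, normal = params[["sd"]],
                      lognormal = params[["sigma"]],
                      exponential = params[["rate"]])
  if (family == "exponential" && scale_par <= 0) {
    abort("Exponential rate must be positive.",
          class = "ricerisk_invariant_error")
  }
  if (family != "exponential" && scale_par < 0) {
    abort("Scale parameter must be non-negative.",
          class = "ricerisk_invariant_error")
  }
  structure(
    list(family = family, params = params, n = n,
         log_likelihood = log_likelihood, aic = aic,
         truncate_at_zero = isTRUE(truncate_at_zero)),
    class = "fitted_distribution"
  )
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat(sprintf("<fitted_distribution: %s(%s)>\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", ")))
  if (!is.na(x$aic)) {
    cat(sprintf("  n = %d, logLik = %.3f, AIC = %.3f\n", x$n,
                x$log_likelihood, x$aic))
  }
  cat(sprintf("  truncate_at_zero = %s\n", x$truncate_at_zero))
  invisible(x)
}

n_free_params <- function(family) {
  switch(family, normal = 2L, lognormal = 2L, exponential = 1L)
}

#' Fit candidate concentration distributions by maximum likelihood
#'
#' Fits normal, lognormal and exponential models to iAs concentrations by
#' closed-form maximum likelihood: normal mean/sd with the MLE divisor n
#' (not n-1), lognormal mean/MLE-sd of log values, exponential rate
#' 1/mean. Each fit carries its log-likelihood and AIC
#' (\eqn{2k - 2\ell}, k = 2, 2, 1 free parameters).
#'
#' Non-positive values cannot enter the lognormal likelihood; they are
#' excluded from that fit only (with a message) while the normal and
#' exponential fits use all values.
#'
#' @param values Numeric vector of concentrations (ng/g), length >= 2.
#' @param truncate_at_zero Truncation flag attached to each returned fit
#'   (a sampling convention, not part of the likelihood).
#' @return An object of class `concentration_fits`: a named list of
#'   `fitted_distribution` objects, one per family.
#' @examples
#' fits <- fit_concentration(c(80, 95, 110, 130, 72, 101))
#' tidy(fits)
#' select_best(fits)
#' @export
fit_concentration <- function(values, truncate_at_zero = TRUE) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("Need at least 2 values to fit.",
          class = "ricerisk_data_error")
  }
  n <- length(values)

  m <- mean(values)
  s_mle <- sqrt(mean((values - m)^2))
  ll_norm <- sum(dnorm(values, m, s_mle, log = TRUE))
  norm_fit <- fitted_distribution("normal", mean = m, sd = s_mle, n = n,
                                  log_likelihood = ll_norm,
                                  aic = 2 * 2 - 2 * ll_norm,
                                  truncate_at_zero = truncate_at_zero)

  pos <- values[values > 0]
  n_dropped <- n - length(pos)
  if (n_dropped > 0) {
    inform(sprintf("Excluded %d non-positive value(s) from the lognormal fit.",
                   n_dropped))
  }
  if (length(pos) < 2) {
    abort("Fewer than 2 positive values; lognormal fit impossible.",
          class = "ricerisk_data_error")
  }
  lx <- log(pos)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  ll_lnorm <- sum(dlnorm(pos, mu, sigma, log = TRUE))
  lnorm_fit <- fitted_distribution("lognormal", mu = mu, sigma = sigma,
                                   n = length(pos),
                                   log_likelihood = ll_lnorm,
                                   aic = 2 * 2 - 2 * ll_lnorm,
                                   truncate_at_zero = truncate_at_zero)

  rate <- 1 / m
  ll_exp <- sum(dexp(values, rate, log = TRUE))
  exp_fit <- fitted_distribution("exponential", rate = rate, n = n,
                                 log_likelihood = ll_exp,
                                 aic = 2 * 1 - 2 * ll_exp,
                                 truncate_at_zero = truncate_at_zero)

  structure(
    list(normal = norm_fit, lognormal = lnorm_fit, exponential = exp_fit,
         n_lognormal_excluded = n_dropped),
    class = "concentration_fits"
  )
}

#' Select the best-fitting distribution by AIC
#'
#' Returns the candidate with the lowest AIC. Ties are broken by the fixed
#' family order normal, lognormal, exponential (fewest distributional
#' assumptions about skew first), so selection is deterministic.
#'
#' @param fits A `concentration_fits` object or list of
#'   `fitted_distribution`s.
#' @return The selected `fitted_distribution`.
#' @export
select_best <- function(fits) {
  if (inherits(fits, "concentration_fits")) {
    fits <- fits[fit_families]
  }
  fits <- Filter(function(f) inherits(f, "fitted_distribution"), fits)
  if (length(fits) == 0) {
    abort("No fits to select from.", class = "ricerisk_usage_error")
  }
  fam_rank <- match(vapply(fits, `[[`, "", "family"), fit_families)
  aics <- vapply(fits, `[[`, 0, "aic")
  ord <- order(aics, fam_rank)
  fits[[ord[1]]]
}

#' @exportS3Method generics::tidy
tidy.concentration_fits <- function(x, ...) {
  best <- select_best(x)
  purrr::map_dfr(x[fit_families], function(f) {
    tibble::tibble(
      family = f$family,
      param1 = f$params[[1]],
      param2 = if (length(f$params) > 1) f$params[[2]] else NA_real_,
      n = f$n,
      log_likelihood = f$log_likelihood,
      aic = f$aic,
      selected = identical(f$family, best$family)
    )
  })
}

#' @export
print.concentration_fits <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

lognormal_logscale_params <- function(dist, param_convention) {
  mu <- dist$params[["mu"]]
  sigma <- dist$params[["sigma"]]
  if (param_convention == "arithmetic") {
    # (mu, sigma) read as arithmetic mean/sd; convert to log-scale params.
    if (mu <= 0) {
      abort("Arithmetic-convention lognormal mean must be positive.",
            class = "ricerisk_usage_error")
    }
    sdlog2 <- log(1 + (sigma / mu)^2)
    c(meanlog = log(mu) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  } else {
    c(meanlog = mu, sdlog = sigma)
  }
}

#' Draw i.i.d. concentrations from a fitted distribution
#'
#' For a normal family with `truncate_at_zero`, negative draws are
#' replaced by rejection resampling so every output is non-negative. For
#' the lognormal family `param_convention` chooses how `(mu, sigma)` are
#' read: `"log_scale"` (default, the statistically standard reading — mean
#' and sd of log concentration) or `"arithmetic"` (mean and sd of the
#' concentration itself, converted internally). The arithmetic mode exists
#' because conflating the two conventions is a recurrent pitfall in
#' published risk assessments and the package can reproduce either
#' behaviour.
#'
#' @param dist A `fitted_distribution`.
#' @param n Number of draws, >= 1.
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @param param_convention `"log_scale"` or `"arithmetic"`.
#' @return Numeric vector of length `n` (ng/g), with attribute
#'   `truncation_resamples` giving the number of rejected negative draws.
#' @export
sample_concentrations <- function(dist, n, seed = NULL,
                                  param_convention = c("log_scale", "arithmetic")) {
  param_convention <- match.arg(param_convention)
  if (!inherits(dist, "fitted_distribution")) {
    abort("`dist` must be a fitted_distribution.",
          class = "ricerisk_usage_error")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a positive count.", class = "ricerisk_usage_error")
  }
  n <- as.integer(n)
  with_seed(seed, {
    resamples <- 0L
    draws <- switch(dist$family,
      normal = {
        x <- rnorm(n, dist$params[["mean"]], dist$params[["sd"]])
        if (dist$truncate_at_zero) {
          while (any(neg <- x < 0)) {
            resamples <- resamples + sum(neg)
            x[neg] <- rnorm(sum(neg), dist$params[["mean"]],
                            dist$params[["sd"]])
          }
        }
        x
      },
      lognormal = {
        p <- lognormal_logscale_params(dist, param_convention)
        rlnorm(n, p[["meanlog"]], p[["sdlog"]])
      },
      exponential = rexp(n, dist$params[["rate"]])
    )
    attr(draws, "truncation_resamples") <- resamples
    draws
  })
}

#' Closed-form mean of a fitted distribution
#'
#' Normal: the mean, or the zero-truncated mean
#' \eqn{\mu + \sigma\,\phi(\mu/\sigma)/\Phi(\mu/\sigma)} when
#' `truncate_at_zero` is set. Lognormal (log-scale convention):
#' \eqn{\exp(\mu + \sigma^2/2)}; arithmetic convention: `mu` itself.
#' Exponential: `1/rate`. Used as the linearity oracle for Monte Carlo
#' validation.
#'
#' @inheritParams sample_concentrations
#' @return Mean concentration, ng/g.
#' @export
distribution_mean <- function(dist,
                              param_convention = c("log_scale", "arithmetic")) {
  param_convention <- match.arg(param_convention)
  if (!inherits(dist, "fitted_distribution")) {
    abort("`dist` must be a fitted_distribution.",
          class = "ricerisk_usage_error")
  }
  switch(dist$family,
    normal = {
      m <- dist$params[["mean"]]
      s <- dist$params[["sd"]]
      if (dist$truncate_at_zero && s > 0) {
        a <- m / s
        m + s * dnorm(a) / pnorm(a)
      } else {
        m
      }
    },
    lognormal = {
      if (param_convention == "arithmetic") {
        dist$params[["mu"]]
      } else {
        exp(dist$params[["mu"]] + dist$params[["sigma"]]^2 / 2)
      }
    },
    exponential = 1 / dist$params[["rate"]]
  )
}

#' Export fit results as JSON
#'
#' @param fits A `concentration_fits` object.
#' @param path Output file.
#' @return The tidied fit table, invisibly.
#' @export
write_fit_json <- function(fits, path) {
  tab <- tidy(fits)
  payload <- list(
    fits = tab,
    selected_family = tab$family[tab$selected][1],
    n_lognormal_excluded = fits$n_lognormal_excluded
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(tab)
}
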