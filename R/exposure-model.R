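# Single locus for the ng/g -> mg/g unit conversion used by the dose
# equation; applied nowhere else so a unit error has one possible home.
NG_PER_G_TO_MG_PER_G <- 1e-6

#' Average daily dose of iAs for each age group
#'
#' Evaluates the chronic average daily dose
#' \deqn{ADD_j = \frac{C \times IR_j \times ED_j \times EF_j}{BW_j \times AT_j}}
#' with the averaging time defined as \eqn{AT_j = ED_j \times 365} days, so
#' the exposure duration cancels and
#' \eqn{ADD_j = C_{mg/g} \, IR_j \, EF_j / (365 \, BW_j)}. Concentration is
#' supplied in ng/g and converted to mg/g internally (factor 1e-6); the
#' result is in mg iAs per kg body weight per day.
#'
#' @param table An [as_exposure_table()] tibble (or a single-row data frame
#'   with its columns).
#' @param concentration_ng_g Scalar iAs concentration in ng per g raw rice.
#' @return A tibble with columns `label` and `add` (mg/kg-day), one row per
#'   age group.
#' @examples
#' tbl <- tibble::tibble(
#'   label = "adult", age_start = 0, age_end = 70, exposure_duration = 70,
#'   ingestion_rate_g_day = 167, body_weight_kg = 60,
#'   exposure_frequency_d_yr = 312.85
#' )
#' compute_add(tbl, 100)
#' @export
compute_add <- function(table, concentration_ng_g) {
  table <- as_exposure_table(table)
  if (!is.numeric(concentration_ng_g) || length(concentration_ng_g) != 1L ||
      is.na(concentration_ng_g)) {
    abort("`concentration_ng_g` must be a single number.",
          class = "ricerisk_usage_error")
  }
  if (concentration_ng_g < 0) {
    abort("Concentration must be non-negative.",
          class = "ricerisk_domain_error")
  }
  c_mg_g <- concentration_ng_g * NG_PER_G_TO_MG_PER_G
  tibble::tibble(
    label = table$label,
    add = c_mg_g * table$ingestion_rate_g_day *
      table$exposure_frequency_d_yr / (table$body_weight_kg * 365)
  )
}

#' Per-age-group cancer risk and hazard quotient terms
#'
#' The incremental cancer risk contribution of age group j is
#' \eqn{ADD_j \times SF \times ED_j / LT}; the fractional hazard quotient is
#' \eqn{(ADD_j / RfD) \times ED_j / LT}. Both are dimensionless; the
#' \eqn{ED_j/LT} factor weights each group by its share of the lifetime.
#'
#' @param add Average daily dose(s), mg/kg-day (vectorised).
#' @param exposure_duration Exposure duration(s) ED_j, years (vectorised).
#' @param constants A [risk_constants()] object.
#' @return Numeric vector of the same length as `add`.
#' @examples
#' cancer_risk_term(2.3857e-4, 10, risk_constants())
#' hq_term(2.3857e-4, 10, risk_constants())
#' @export
cancer_risk_term <- function(add, exposure_duration, constants = risk_constants()) {
  check_terms_input(add, constants)
  add * constants$slope_factor * exposure_duration / constants$lifetime_years
}

#' @rdname cancer_risk_term
#' @export
hq_term <- function(add, exposure_duration, constants = risk_constants()) {
  check_terms_input(add, constants)
  (add / constants$reference_dose) * exposure_duration / constants$lifetime_years
}

check_terms_input <- function(add, constants) {
  if (!inherits(constants, "risk_constants")) {
    abort("`constants` must be created with risk_constants().",
          class = "ricerisk_usage_error")
  }
  if (any(add < 0, na.rm = TRUE)) {
    abort("Average daily dose must be non-negative.",
          class = "ricerisk_domain_error")
  }
  invisible(TRUE)
}

#' Per-group risk terms and lifetime totals at a fixed concentration
#'
#' `age_risk_terms()` evaluates dose, cancer-risk and HQ terms for every
#' age group at one deterministic concentration; `lifetime_totals()` sums a
#' term table into the lifetime ILCR and HQ. For any fixed concentration
#' the two totals obey the algebraic identity
#' \eqn{ILCR = HQ \times SF \times RfD}.
#'
#' @inheritParams compute_add
#' @param constants A [risk_constants()] object.
#' @return `age_risk_terms()`: a tibble with columns `label`, `add`,
#'   `cancer_risk`, `hq`. `lifetime_totals()`: a one-row tibble with
#'   columns `ilcr` and `hq` (zero for an empty term table).
#' @examples
#' tbl <- generate_exposure_table()
#' terms <- age_risk_terms(tbl, 100)
#' lifetime_totals(terms)
#' @export
age_risk_terms <- function(table, concentration_ng_g,
                           constants = risk_constants()) {
  table <- as_exposure_table(table,
                             lifetime_years = constants$lifetime_years)
  doses <- compute_add(table, concentration_ng_g)
  tibble::tibble(
    label = doses$label,
    add = doses$add,
    cancer_risk = cancer_risk_term(doses$add, table$exposure_duration, constants),
    hq = hq_term(doses$add, table$exposure_duration, constants)
  )
}

#' @rdname age_risk_terms
#' @param terms A data frame with numeric columns `cancer_risk` and `hq`
#'   (as returned by `age_risk_terms()`); may have zero rows.
#' @export
lifetime_totals <- function(terms) {
  if (!is.data.frame(terms) ||
      !all(c("cancer_risk", "hq") %in% names(terms))) {
    abort("`terms` must have `cancer_risk` and `hq` columns.",
          class = "ricerisk_usage_error")
  }
  tibble::tibble(
    ilcr = sum(terms$cancer_risk),
    hq = sum(terms$hq)
  )
}

#' Deterministic lifetime risk at a fixed mean concentration
#'
#' Because the dose and risk equations are linear in concentration, the
#' Monte Carlo mean ILCR equals the deterministic ILCR evaluated at the
#' concentration distribution's mean. This closed form is the oracle used
#' to validate the simulation engine.
#'
#' @inheritParams age_risk_terms
#' @param mean_c Mean concentration, ng/g.
#' @return A one-row tibble with columns `ilcr` and `hq`.
#' @export
closed_form_ilcr <- function(table, mean_c, constants = risk_constants()) {
  lifetime_totals(age_risk_terms(table, mean_c, constants))
}
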