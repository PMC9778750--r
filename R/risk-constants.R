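#' Toxicological constants for the iAs risk equations
#'
#' Bundles the three constants shared by the cancer and non-cancer risk
#' equations: the oral cancer slope factor SF, the chronic oral reference
#' dose RfD, and the lifetime LT over which age-group contributions are
#' weighted. Defaults are the EPA values for inorganic arsenic.
#'
#' @param slope_factor Cancer potency per unit dose, (mg/kg-day)^-1.
#'   Default 1.5 (oral iAs).
#' @param reference_dose Chronic oral dose assumed without appreciable
#'   non-cancer risk, mg/kg-day. Default 0.003 (oral iAs).
#' @param lifetime_years Lifetime used to weight age-group contributions,
#'   years. Default 70.
#'
#' @return An object of class `risk_constants`.
#' @examples
#' risk_constants()
#' risk_constants(reference_dose = 0.015) # alternative RfD used in some studies
#' @export
risk_constants <- function(slope_factor = 1.5,
                           reference_dose = 0.003,
                           lifetime_years = 70) {
  for (nm in c("slope_factor", "reference_dose", "lifetime_years")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm),
            class = "ricerisk_invariant_error")
    }
  }
  structure(
    list(
      slope_factor = slope_factor,
      reference_dose = reference_dose,
      lifetime_years = lifetime_years
    ),
    class = "risk_constants"
  )
}

#' @export
print.risk_constants <- function(x, ...) {
  cat("<risk_constants>\n")
  cat(sprintf("  slope factor (SF):    %g (mg/kg-day)^-1\n", x$slope_factor))
  cat(sprintf("  reference dose (RfD): %g mg/kg-day\n", x$reference_dose))
  cat(sprintf("  lifetime (LT):        %g years\n", x$lifetime_years))
  invisible(x)
}
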