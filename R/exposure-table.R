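exposure_table_cols <- c(
  "label", "age_start", "age_end", "exposure_duration",
  "ingestion_rate_g_day", "body_weight_kg", "exposure_frequency_d_yr"
)

#' Validate and classify an age-stratified exposure table
#'
#' An exposure table is a tibble with one row per age bin and columns
#' `label`, `age_start`, `age_end`, `exposure_duration` (ED, years),
#' `ingestion_rate_g_day` (IR, g raw rice/day), `body_weight_kg` (BW) and
#' `exposure_frequency_d_yr` (EF, days/year). `as_exposure_table()` checks
#' the structural invariants and attaches the `exposure_table` class:
#'
#' * every ED is positive and equals `age_end - age_start` (tolerance 1e-9);
#' * bins are contiguous and non-overlapping;
#' * EF lies in \[0, 365\]; IR is non-negative; BW is positive;
#' * the summed ED does not exceed `lifetime_years`.
#'
#' @param x A data frame with the columns above.
#' @param lifetime_years Lifetime bound for the summed exposure duration.
#' @return `x` as a tibble with class `exposure_table`.
#' @seealso [generate_exposure_table()] for a constraint-satisfying default
#'   table, [read_exposure_table()] for file input.
#' @export
as_exposure_table <- function(x, lifetime_years = 70) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame.", class = "ricerisk_usage_error")
  }
  missing_cols <- setdiff(exposure_table_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Exposure table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ricerisk_usage_error")
  }
  x <- tibble::as_tibble(x)[exposure_table_cols]
  if (nrow(x) == 0) {
    abort("Exposure table must have at least one age bin.",
          class = "ricerisk_usage_error")
  }
  ed <- x$exposure_duration
  if (any(ed <= 0)) {
    abort("All exposure durations must be positive.",
          class = "ricerisk_invariant_error")
  }
  if (any(abs(ed - (x$age_end - x$age_start)) > 1e-9)) {
    abort("exposure_duration must equal age_end - age_start for every bin.",
          class = "ricerisk_invariant_error")
  }
  if (nrow(x) > 1 &&
      any(abs(x$age_start[-1] - x$age_end[-nrow(x)]) > 1e-9)) {
    abort("Age bins must be contiguous and non-overlapping.",
          class = "ricerisk_invariant_error")
  }
  if (any(x$exposure_frequency_d_yr < 0 | x$exposure_frequency_d_yr > 365)) {
    abort("exposure_frequency_d_yr must lie in [0, 365].",
          class = "ricerisk_invariant_error")
  }
  if (any(x$ingestion_rate_g_day < 0)) {
    abort("ingestion_rate_g_day must be non-negative.",
          class = "ricerisk_invariant_error")
  }
  if (any(x$body_weight_kg <= 0)) {
    abort("body_weight_kg must be positive.",
          class = "ricerisk_invariant_error")
  }
  if (sum(ed) > lifetime_years + 1e-9) {
    abort(sprintf("Summed exposure duration (%.4g y) exceeds the lifetime (%g y).",
                  sum(ed), lifetime_years),
          class = "ricerisk_invariant_error")
  }
  class(x) <- unique(c("exposure_table", class(x)))
  x
}

#' Read or write an exposure table as CSV
#'
#' The on-disk format is a plain CSV with the header
#' `label, age_start, age_end, exposure_duration, ingestion_rate_g_day,
#' body_weight_kg, exposure_frequency_d_yr`.
#'
#' @param path File path.
#' @param lifetime_years Passed to [as_exposure_table()].
#' @return `read_exposure_table()` returns a validated `exposure_table`
#'   tibble; `write_exposure_table()` returns `table` invisibly.
#' @export
read_exposure_table <- function(path, lifetime_years = 70) {
  if (!file.exists(path)) {
    abort(sprintf("Exposure table file not found: %s", path),
          class = "ricerisk_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_exposure_table(x, lifetime_years = lifetime_years)
}

#' @rdname read_exposure_table
#' @param table An `exposure_table`.
#' @export
write_exposure_table <- function(table, path) {
  table <- as_exposure_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(table)
}
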