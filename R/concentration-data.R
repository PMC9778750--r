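concentration_cols <- c(
  "sample_id", "rice_type", "origin", "city", "state", "variety",
  "ias_ng_g", "cd_ng_g"
)

#' Read an iAs concentration dataset from CSV
#'
#' One row per rice sample. Required columns: `sample_id`, `rice_type`
#' (`white`/`brown`), `ias_ng_g` (ng iAs per g raw rice). Optional
#' metadata: `origin` (`farm`/`market`; missing values become `unknown`),
#' `city`, `state`, `variety`, `cd_ng_g` (cadmium). Rows with negative or
#' missing `ias_ng_g` are dropped with a warning; an input yielding no
#' valid rows is an error.
#'
#' @param path CSV file path.
#' @return A tibble with the standard concentration columns.
#' @export
read_concentration_data <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Concentration file not found: %s", path),
          class = "ricerisk_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "rice_type", "ias_ng_g")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Concentration file is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ricerisk_io_error")
  }
  for (nm in setdiff(concentration_cols, names(x))) {
    x[[nm]] <- if (nm == "cd_ng_g") NA_real_ else NA_character_
  }
  x <- tibble::as_tibble(x)[concentration_cols]
  x$rice_type <- tolower(as.character(x$rice_type))
  bad_type <- !x$rice_type %in% c("white", "brown")
  if (any(bad_type)) {
    abort(sprintf("rice_type must be 'white' or 'brown' (%d invalid rows).",
                  sum(bad_type)),
          class = "ricerisk_domain_error")
  }
  x$origin <- tolower(as.character(x$origin))
  x$origin[is.na(x$origin) | !x$origin %in% c("farm", "market")] <- "unknown"
  bad <- is.na(x$ias_ng_g) | x$ias_ng_g < 0
  if (any(bad)) {
    warn(sprintf("Dropped %d row(s) with missing or negative ias_ng_g.",
                 sum(bad)))
    x <- x[!bad, ]
  }
  if (nrow(x) == 0) {
    abort("No valid concentration rows after filtering.",
          class = "ricerisk_data_error")
  }
  x
}

#' @rdname read_concentration_data
#' @param data A concentration tibble.
#' @export
write_concentration_data <- function(data, path) {
  readr::write_csv(data[intersect(concentration_cols, names(data))], path,
                   progress = FALSE)
  invisible(data)
}

#' Descriptive statistics of iAs concentration, optionally by group
#'
#' @param data A concentration tibble (needs `ias_ng_g`).
#' @param group_by Optional name of a metadata column (`rice_type`,
#'   `origin`, `city`, `state`, `variety`) to stratify by.
#' @return A tibble with one row overall or per group: `n`, `mean`, `sd`
#'   (sample standard deviation, divisor n-1; `NA` when n < 2), `min`,
#'   `max`.
#' @examples
#' ds <- generate_concentration_data(seed = 1)
#' concentration_stats(ds, group_by = "rice_type")
#' @export
concentration_stats <- function(data, group_by = NULL) {
  if (!is.data.frame(data) || !"ias_ng_g" %in% names(data)) {
    abort("`data` must contain an `ias_ng_g` column.",
          class = "ricerisk_usage_error")
  }
  if (!is.null(group_by)) {
    if (!is.character(group_by) || length(group_by) != 1L ||
        !group_by %in% names(data)) {
      abort(sprintf("Unknown grouping column: %s",
                    paste(group_by, collapse = ", ")),
            class = "ricerisk_usage_error")
    }
    data <- dplyr::group_by(data, dplyr::across(dplyr::all_of(group_by)))
  }
  out <- dplyr::summarise(
    data,
    n = dplyr::n(),
    mean = mean(.data$ias_ng_g),
    sd = if (dplyr::n() >= 2) stats::sd(.data$ias_ng_g) else NA_real_,
    min = min(.data$ias_ng_g),
    max = max(.data$ias_ng_g),
    .groups = "drop"
  )
  out
}

#' Pearson correlation between paired concentration measurements
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform on n - 2 degrees of freedom, as used to probe As-Cd
#' co-occurrence (a near-zero correlation argues against a shared
#' soil-chemistry driver such as unsaturated cultivation).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.",
          class = "ricerisk_usage_error")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    abort("Need at least 3 complete pairs.",
          class = "ricerisk_data_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation is undefined when either vector has zero variance.",
          class = "ricerisk_data_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x)
  )
}

#' Welch two-sample t-test on concentration groups
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, used e.g. to compare white vs brown rice iAs levels.
#'
#' @param a,b Numeric vectors, each with n >= 2 and positive variance.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 observations.",
          class = "ricerisk_data_error")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # t.test errors on two constant groups; identical constants mean no
    # detectable difference, different constants an infinite separation.
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = length(a) + length(b) - 2,
                            p_value = 1, mean_a = mean(a), mean_b = mean(b)))
    }
    abort("Both groups are constant; Welch test undefined.",
          class = "ricerisk_data_error")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}
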