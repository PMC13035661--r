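#' Time-normalised evolution marker ("+" measure)
#'
#' Standardises the change between two scans by the inter-scan interval and
#' adds it to the baseline value, yielding an estimate of the measurement
#' one year after the first scan:
#' `m_plus = m1 + (m2 - m1) * year_length / delta_days`.
#'
#' Intervals shorter than 30 days trigger a warning: linear extrapolation
#' from very short intervals is unstable.
#'
#' @param m1,m2 Marker values at the first and second scan (same units).
#' @param delta_days Days between scans, `> 0`. Vectorised over patients.
#' @param year_length Days per year used for normalisation (default 365).
#' @return The annualised marker value(s), in the marker's units.
#' @export
#' @examples
#' annualize_measure(40, 44, 182.5)  # doubling time coefficient -> 48
annualize_measure <- function(m1, m2, delta_days, year_length = 365) {
  if (any(!is.finite(delta_days)) || any(delta_days <= 0)) {
    abort("delta_days must be positive")
  }
  if (any(delta_days < 30)) {
    warn("delta_days < 30: one-year extrapolation from a very short interval is unstable")
  }
  m1 + (m2 - m1) * (year_length / delta_days)
}

#' Add evolution markers to a paired cohort table
#'
#' For each marker base name `m` with columns `<m>_t1` and `<m>_t2`, adds
#' `<m>_plus` computed by [annualize_measure()]. The interval is taken from
#' a `delta_days` column, or computed from `t1_date` / `t2_date`.
#'
#' @param data Cohort data frame (one row per patient).
#' @param markers Character vector of marker base names.
#' @param year_length Days per year (default 365).
#' @return `data` with the `<marker>_plus` columns appended, as a tibble.
#' @export
annualize_cohort <- function(data, markers, year_length = 365) {
  data <- tibble::as_tibble(data)
  if (!"delta_days" %in% names(data)) {
    if (!all(c("t1_date", "t2_date") %in% names(data))) {
      abort("need a delta_days column or t1_date/t2_date columns")
    }
    data$delta_days <- as.numeric(as.Date(data$t2_date) - as.Date(data$t1_date))
  }
  for (m in markers) {
    c1 <- paste0(m, "_t1"); c2 <- paste0(m, "_t2")
    if (!all(c(c1, c2) %in% names(data))) {
      abort(paste0("missing columns for marker '", m, "': ", c1, ", ", c2))
    }
    data[[paste0(m, "_plus")]] <-
      annualize_measure(data[[c1]], data[[c2]], data$delta_days, year_length)
  }
  data
}
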