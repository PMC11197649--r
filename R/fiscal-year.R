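# Fiscal-year period model. The Ethiopian government plans on a 12-month
# fiscal year running 1 July to 30 June (Gregorian), so the default window
# maps fiscal months 1..12 onto calendar period codes "202207".."202306"
# (Ethiopian Fiscal Year 2015). Other windows are plain configuration.

#' Define the fiscal-year reporting window
#'
#' A fiscal year is an ordered sequence of calendar months, identified by
#' DHIS2-style period codes `"YYYYMM"`. Fiscal month indices 1..`n_months`
#' map bijectively onto the codes; any period outside the window is rejected
#' at ingestion.
#'
#' @param start period code of the first fiscal month (default `"202207"`,
#'   i.e. July 2022, the start of Ethiopian Fiscal Year 2015).
#' @param n_months number of months in the window (default 12).
#' @return An object of class `fiscal_year` with elements `start`,
#'   `n_months`, `codes` (character vector of period codes) and `label`.
#' @examples
#' fy <- fiscal_year()
#' fy$codes[c(1, 12)]  # "202207" "202306"
#' @export
fiscal_year <- function(start = "202207", n_months = 12L) {
  if (!grepl("^[0-9]{6}$", start)) {
    stop_config(sprintf("fiscal-year start '%s' is not a YYYYMM period code", start))
  }
  y <- as.integer(substr(start, 1, 4))
  m <- as.integer(substr(start, 5, 6))
  if (m < 1 || m > 12) {
    stop_config(sprintf("fiscal-year start '%s' has month outside 01-12", start))
  }
  n_months <- as.integer(n_months)
  if (n_months < 1) stop_config("n_months must be at least 1")
  idx <- seq_len(n_months) - 1L
  yy <- y + (m - 1L + idx) %/% 12L
  mm <- (m - 1L + idx) %% 12L + 1L
  codes <- sprintf("%04d%02d", yy, mm)
  structure(
    list(start = start, n_months = n_months, codes = codes,
         label = paste(codes[1], codes[n_months], sep = "-")),
    class = "fiscal_year"
  )
}

#' @export
print.fiscal_year <- function(x, ...) {
  cat(sprintf("<fiscal_year> %d months, %s\n", x$n_months, x$label))
  invisible(x)
}

#' Convert period codes to fiscal-month indices
#'
#' @param period character vector of `"YYYYMM"` period codes.
#' @param fy a [fiscal_year()] window.
#' @return integer fiscal-month indices (1-based).
#' @export
period_to_month <- function(period, fy = fiscal_year()) {
  i <- match(as.character(period), fy$codes)
  if (anyNA(i)) {
    bad <- unique(period[is.na(i)])
    stop_domain(sprintf(
      "period(s) outside the fiscal-year window %s: %s",
      fy$label, oxford(bad)
    ))
  }
  as.integer(i)
}

#' Convert fiscal-month indices to period codes
#'
#' @param index integer fiscal-month indices.
#' @inheritParams period_to_month
#' @return character period codes.
#' @export
month_to_period <- function(index, fy = fiscal_year()) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L) || any(index > fy$n_months)) {
    stop_domain(sprintf("fiscal-month index outside 1..%d", fy$n_months))
  }
  fy$codes[index]
}
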