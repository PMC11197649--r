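# Ingestion of DHIS2-style long CSV exports and facility registries into the
# canonical facility-month panel, plus the tabular writers.

#' Construct a validated monthly panel
#'
#' The canonical panel is a long tibble with one row per reported
#' (facility, element, month) cell. Absent keys mean "not reported" — which,
#' because DHIS2 does not transmit zero counts, may be either a true missing
#' report or a month with no activity.
#'
#' @param records tibble with columns `facility_id`, `element_code`,
#'   `month` (fiscal-month index) and `value` (non-negative integer count).
#' @param fiscal_year the [fiscal_year()] window the months refer to.
#' @param source provenance label (input path), kept as an attribute.
#' @return a `monthly_panel` tibble, sorted by facility, element, month.
#' @export
monthly_panel <- function(records, fiscal_year = dhisdash::fiscal_year(),
                          source = NA_character_) {
  records <- as_tibble(records)
  need <- c("facility_id", "element_code", "month", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_schema(sprintf("panel is missing column(s): %s", oxford(miss)))
  }
  records <- records[need]
  records$month <- as.integer(records$month)
  if (nrow(records)) {
    if (any(is.na(records$value)) || any(records$value < 0)) {
      stop_domain("panel values must be non-negative counts")
    }
    if (any(records$value != floor(records$value))) {
      stop_domain("panel values must be integer counts")
    }
    if (any(is.na(records$month)) || any(records$month < 1L) ||
        any(records$month > fiscal_year$n_months)) {
      stop_domain(sprintf("panel months must lie in 1..%d", fiscal_year$n_months))
    }
    key <- paste(records$facility_id, records$element_code, records$month)
    if (anyDuplicated(key)) {
      stop_duplicate(sprintf(
        "duplicate (facility, element, month) key(s), first: %s",
        key[duplicated(key)][1]
      ))
    }
  }
  out <- arrange(records, facility_id, element_code, month)
  attr(out, "fiscal_year") <- fiscal_year
  attr(out, "source") <- source
  class(out) <- c("monthly_panel", class(tibble()))
  out
}

# fiscal year attached to a panel, falling back to the default window
panel_fiscal_year <- function(panel) {
  attr(panel, "fiscal_year") %||% fiscal_year()
}

#' Read a DHIS2 long-format CSV export
#'
#' Expects one row per (facility, element, period) with an integer count.
#' Values may carry thousands separators and surrounding whitespace; an
#' empty value cell means "not reported" and the row is dropped (DHIS2 does
#' not transmit zeros, so blank is not zero). Periods outside the configured
#' fiscal-year window are rejected.
#'
#' @param path CSV file with a header row.
#' @param fiscal_year the [fiscal_year()] window; periods outside it error.
#' @param columns named character vector mapping the canonical names
#'   `facility_id`, `element_code`, `period`, `value` to the header names
#'   used in the file.
#' @param duplicates policy for repeated (facility, element, period) keys:
#'   `"error"` (default), `"sum"`, or `"last"`.
#' @return a [monthly_panel()].
#' @export
read_long_export <- function(path,
                             fiscal_year = dhisdash::fiscal_year(),
                             columns = c(facility_id = "facility_id",
                                         element_code = "element_code",
                                         period = "period",
                                         value = "value"),
                             duplicates = c("error", "sum", "last")) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("facility_id", "element_code", "period", "value")
  columns <- columns[need]
  bad <- is.na(columns) | !(columns %in% names(raw))
  if (any(bad)) {
    stop_schema(sprintf("export is missing column(s): %s",
                        oxford(ifelse(is.na(columns[bad]), need[bad], columns[bad]))))
  }
  x <- tibble(
    facility_id = raw[[columns[["facility_id"]]]],
    element_code = raw[[columns[["element_code"]]]],
    period = raw[[columns[["period"]]]],
    value = raw[[columns[["value"]]]]
  )

  # value dialect: strip whitespace and thousands separators; blank = absent
  v <- gsub("[[:space:],\u00a0]", "", x$value)
  blank <- is.na(v) | !nzchar(v)
  x <- x[!blank, , drop = FALSE]
  v <- v[!blank]
  num <- suppressWarnings(as.numeric(v))
  if (anyNA(num)) {
    stop_domain(sprintf("non-numeric value(s): %s", oxford(unique(v[is.na(num)]))))
  }
  if (any(num < 0)) {
    stop_domain(sprintf("negative value(s), first at facility %s",
                        x$facility_id[num < 0][1]))
  }
  if (any(num != floor(num))) {
    stop_domain(sprintf("non-integer value(s): %s",
                        oxford(unique(v[num != floor(num)]))))
  }
  x$value <- num
  x$month <- period_to_month(x$period, fiscal_year)

  key <- paste(x$facility_id, x$element_code, x$month)
  if (anyDuplicated(key)) {
    if (duplicates == "error") {
      stop_duplicate(sprintf(
        "duplicate (facility, element, period) key, first offending: %s",
        paste(x$facility_id[duplicated(key)][1],
              x$element_code[duplicated(key)][1],
              x$period[duplicated(key)][1])
      ))
    } else if (duplicates == "sum") {
      x <- x %>%
        group_by(facility_id, element_code, month) %>%
        summarise(value = sum(value), .groups = "drop")
    } else {
      x <- x[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    }
  }
  monthly_panel(x[c("facility_id", "element_code", "month", "value")],
                fiscal_year = fiscal_year, source = path)
}

#' Write a panel back to a long CSV export
#'
#' Inverse of [read_long_export()]: months are rendered as period codes and
#' rows are written in canonical (facility, element, month) order, so that
#' write-then-read round-trips the record set exactly.
#'
#' @param panel a [monthly_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  fy <- panel_fiscal_year(panel)
  out <- panel %>%
    as_tibble() %>%
    arrange(facility_id, element_code, month) %>%
    mutate(period = month_to_period(month, fy)) %>%
    select(facility_id, element_code, period, value)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a facility registry
#'
#' @param path CSV with columns `facility_id`, `region`, `facility_type`.
#' @param types allowed facility-type labels; extend to accept labels beyond
#'   the closed default set.
#' @param regions optional allowed region labels; `NULL` accepts any label.
#' @return tibble with columns `facility_id`, `region`, `facility_type`,
#'   and derived `sector`.
#' @export
read_facility_registry <- function(path, types = facility_types(),
                                   regions = NULL) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  facility_registry(raw, types = types, regions = regions)
}

#' @rdname read_facility_registry
#' @param x data frame with the registry columns (in-memory constructor).
#' @export
facility_registry <- function(x, types = facility_types(), regions = NULL) {
  x <- as_tibble(x)
  need <- c("facility_id", "region", "facility_type")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_schema(sprintf("registry is missing column(s): %s", oxford(miss)))
  }
  if (anyDuplicated(x$facility_id)) {
    stop_duplicate(sprintf(
      "duplicate facility id(s): %s",
      oxford(unique(x$facility_id[duplicated(x$facility_id)]))
    ))
  }
  unknown <- setdiff(unique(x$facility_type), types)
  if (length(unknown)) {
    stop_domain(sprintf("unknown facility type label(s): %s", oxford(unknown)))
  }
  if (!is.null(regions)) {
    bad <- setdiff(unique(x$region), regions)
    if (length(bad)) {
      stop_domain(sprintf("unknown region label(s): %s", oxford(bad)))
    }
  }
  x %>%
    mutate(sector = facility_sector(facility_type)) %>%
    select(facility_id, region, facility_type, sector)
}

#' Restrict a registry to facilities active during the year
#'
#' Facilities listed in the registry but reporting none of the catalogue
#' elements at any month are dropped from the registry (they contribute
#' nothing to completeness denominators or totals). The panel itself is
#' unchanged. Idempotent.
#'
#' @param panel a [monthly_panel()].
#' @param registry a facility registry.
#' @param elements element codes that define "active" (default: the full
#'   catalogue).
#' @return list with `panel`, the restricted `registry`, and `log`
#'   (`n_listed`, `n_retained`, `n_dropped`, `facility_months` =
#'   retained facilities x fiscal months).
#' @export
restrict_to_active <- function(panel, registry,
                               elements = element_catalogue()$code) {
  fy <- panel_fiscal_year(panel)
  active <- unique(panel$facility_id[panel$element_code %in% elements])
  keep <- registry$facility_id %in% active
  out <- registry[keep, , drop = FALSE]
  list(
    panel = panel,
    registry = out,
    log = list(
      n_listed = nrow(registry),
      n_retained = nrow(out),
      n_dropped = nrow(registry) - nrow(out),
      facility_months = nrow(out) * fy$n_months
    )
  )
}

#' Write a dashboard table to CSV or JSON
#'
#' Percentage columns (names ending in `_pct` or named `percentage`) are
#' rendered with one decimal in CSV output, matching the dashboard display
#' convention; JSON output keeps full precision.
#'
#' @param x a tibble.
#' @param path output path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    y <- as_tibble(x)
    pct_cols <- grep("(_pct$|^percentage$|^average_pct$)", names(y), value = TRUE)
    for (cl in pct_cols) y[[cl]] <- fmt_pct(y[[cl]])
    readr::write_csv(y, path, progress = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null", na = "null")
  }
  invisible(path)
}
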