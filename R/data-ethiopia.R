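# Bundled reference totals for Ethiopian Fiscal Year 2015 (July 2022 -
# June 2023): annual regional element totals for the three study regions,
# and the Addis Ababa health-centre / public-hospital columns of the
# facility-type disaggregation. These published aggregates are the
# fixed-point inputs for regression-testing the indicator arithmetic
# without the national facility-level extract.

#' Bundled EFY-2015 annual totals
#'
#' `efy2015_regional_totals()`: annual counts of elements `i`-`xxiv` for
#' Addis Ababa, Oromia and Somali. `efy2015_addis_type_totals()`: the same
#' elements for Addis Ababa health centres and public hospitals.
#'
#' @return tibble with columns `region`, `element_code`, `value`, plus
#'   `facility_type` for the second form.
#' @export
efy2015_regional_totals <- function() {
  readr::read_csv(catalogue_path("efy2015_regional_totals.csv"),
                  col_types = readr::cols(region = "c", element_code = "c",
                                          value = "d"),
                  progress = FALSE)
}

#' @rdname efy2015_regional_totals
#' @export
efy2015_addis_type_totals <- function() {
  readr::read_csv(catalogue_path("efy2015_addis_type_totals.csv"),
                  col_types = readr::cols(region = "c", facility_type = "c",
                                          element_code = "c", value = "d"),
                  progress = FALSE)
}

#' Turn published annual totals into a one-facility-per-group panel
#'
#' Each region (or region x facility-type) group becomes a single pseudo-facility
#' whose month-1 cell carries the annual total of each element; annual
#' aggregation then reproduces the totals exactly, so printed dashboard
#' tables can be pushed through the pipeline as regression fixtures.
#' Zero totals are skipped (no-zero-reporting semantics).
#'
#' @param totals tibble with `region`, optional `facility_type`,
#'   `element_code`, `value`.
#' @param fiscal_year reporting window of the pseudo-panel.
#' @return list with `panel` (a [monthly_panel()]) and `registry`.
#' @export
totals_to_panel <- function(totals, fiscal_year = dhisdash::fiscal_year()) {
  totals <- as_tibble(totals)
  has_type <- "facility_type" %in% names(totals)
  if (!has_type) totals$facility_type <- "health_centre"
  totals <- totals %>%
    mutate(facility_id = paste0("AGG-", gsub(" ", "_", region), "-",
                                facility_type))
  registry <- totals %>%
    distinct(facility_id, region, facility_type) %>%
    mutate(sector = facility_sector(facility_type))
  panel <- monthly_panel(
    totals %>%
      filter(value > 0) %>%
      transmute(facility_id, element_code, month = 1L, value),
    fiscal_year = fiscal_year, source = "aggregated totals"
  )
  list(panel = panel, registry = registry)
}
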