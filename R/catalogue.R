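# Catalogues: the 26 monthly data elements, the 14 numerator/denominator
# performance indicators built from them, the facility-type applicability
# matrix, and the external reference ranges. All four are shipped as
# editable YAML under inst/extdata so that country adaptations are data
# changes, not code changes.

catalogue_path <- function(file) {
  p <- system.file("extdata", file, package = "dhisdash")
  if (!nzchar(p)) stop_config(sprintf("bundled catalogue '%s' not found", file))
  p
}

#' Default region labels
#' @return character vector of the three default regions.
#' @export
default_regions <- function() c("Addis Ababa", "Oromia", "Somali")

#' Facility-type labels
#'
#' The closed default set of facility types. `facility_sector()` derives the
#' public/private sector from the type.
#'
#' @return character vector of the five facility types.
#' @export
facility_types <- function() {
  c("health_post", "health_centre", "public_hospital",
    "private_clinic", "private_hospital")
}

#' @rdname facility_types
#' @param type character vector of facility-type labels.
#' @export
facility_sector <- function(type) {
  ifelse(type %in% c("private_clinic", "private_hospital"),
         "private", "public")
}

hospital_types <- function() c("public_hospital", "private_hospital")

#' Data-element catalogue
#'
#' The 26 monthly data elements, keyed by roman-numeral codes `i`..`xxvi`,
#' each with a display name and a programme area. Elements `xxv` (total
#' outpatient visits) and `xxvi` (oral contraceptive acceptors) feed the
#' completeness and service-volume analyses only and never enter the 14
#' indicators.
#'
#' @param path optional path to an alternative elements YAML.
#' @return tibble with columns `code`, `name`, `programme_area`.
#' @export
element_catalogue <- function(path = NULL) {
  path <- path %||% catalogue_path("elements.yaml")
  y <- yaml::read_yaml(path)
  out <- purrr::map_dfr(y$elements, as_tibble)
  need <- c("code", "name", "programme_area")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop_schema(sprintf("elements catalogue missing field(s): %s", oxford(miss)))
  }
  if (anyDuplicated(out$code)) {
    stop_duplicate(sprintf(
      "duplicate element code(s): %s", oxford(unique(out$code[duplicated(out$code)]))
    ))
  }
  out[need]
}

#' Performance-indicator catalogue
#'
#' The 14 indicators, each binding a numerator element to a denominator
#' element (e.g. third-dose over first-dose pentavalent vaccine for
#' immunisation retention) with a performance domain label.
#'
#' @param path optional path to an alternative indicators YAML.
#' @param elements element catalogue used to validate the bindings.
#' @return tibble with columns `indicator_id`, `name`, `numerator`,
#'   `denominator`, `performance_domain`.
#' @export
indicator_catalogue <- function(path = NULL, elements = element_catalogue()) {
  path <- path %||% catalogue_path("indicators.yaml")
  y <- yaml::read_yaml(path)
  out <- purrr::map_dfr(y$indicators, as_tibble)
  need <- c("indicator_id", "name", "numerator", "denominator", "performance_domain")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop_schema(sprintf("indicator catalogue missing field(s): %s", oxford(miss)))
  }
  out$indicator_id <- as.integer(out$indicator_id)
  if (anyDuplicated(out$indicator_id)) stop_duplicate("duplicate indicator ids")
  if (any(out$numerator == out$denominator)) {
    stop_config("an indicator may not use the same element as numerator and denominator")
  }
  unknown <- setdiff(c(out$numerator, out$denominator), elements$code)
  if (length(unknown)) {
    stop_config(sprintf(
      "indicator catalogue references unknown element(s): %s", oxford(unknown)
    ))
  }
  out[need]
}

#' Facility-type applicability of data elements
#'
#' Not every element is collected at every facility tier: health posts, the
#' rural community tier, do not run antenatal syphilis/HIV testing, ART,
#' tuberculosis, hypertension, diabetes or antibiotic-stewardship reporting.
#' An (element, facility_type) pair absent from the applicability set yields
#' an `NA` indicator cell in disaggregated tables, distinct from a zero
#' total.
#'
#' @param path optional path to an alternative applicability YAML.
#' @param elements element catalogue defining the full code set.
#' @return tibble with columns `facility_type`, `element_code`, `applicable`.
#' @export
type_applicability <- function(path = NULL, elements = element_catalogue()) {
  path <- path %||% catalogue_path("applicability.yaml")
  y <- yaml::read_yaml(path)$applicability
  types <- names(y)
  unknown_type <- setdiff(types, facility_types())
  if (length(unknown_type)) {
    stop_config(sprintf("unknown facility type(s) in applicability: %s",
                        oxford(unknown_type)))
  }
  rows <- purrr::map_dfr(types, function(ft) {
    codes <- y[[ft]]
    if (identical(codes, "all")) codes <- elements$code
    unknown <- setdiff(codes, elements$code)
    if (length(unknown)) {
      stop_config(sprintf("applicability for %s names unknown element(s): %s",
                          ft, oxford(unknown)))
    }
    tibble(facility_type = ft, element_code = codes)
  })
  tidyr::crossing(facility_type = types, element_code = elements$code) %>%
    left_join(rows %>% mutate(applicable = TRUE),
              by = c("facility_type", "element_code")) %>%
    mutate(applicable = !is.na(applicable))
}

#' External reference ranges for indicator triangulation
#'
#' One reference interval per indicator (a point estimate has `low == high`),
#' drawn from household surveys (DHS), facility assessments (SPA), ministry
#' annual reports and WHO/UNAIDS global estimates. Used by
#' [assess_validity()].
#'
#' @param path optional path to an alternative references YAML.
#' @return tibble with columns `indicator_id`, `low`, `high`, `source`.
#' @export
reference_ranges <- function(path = NULL) {
  path <- path %||% catalogue_path("references.yaml")
  y <- yaml::read_yaml(path)
  out <- purrr::map_dfr(y$references, as_tibble)
  out$indicator_id <- as.integer(out$indicator_id)
  if (anyDuplicated(out$indicator_id)) stop_duplicate("duplicate reference entries")
  if (any(out$low < 0) || any(out$low > out$high)) {
    stop_config("reference ranges must satisfy 0 <= low <= high")
  }
  out[c("indicator_id", "low", "high", "source")]
}
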