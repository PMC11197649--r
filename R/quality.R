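# Data-quality dimensions on the facility-month panel: reporting
# completeness, extreme positive outlier screening and censoring, and
# internal consistency of numerator/denominator indicators. (External
# validity is handled by assess_validity().)

normalise_grouping <- function(by) {
  if (identical(by, "overall")) return(character(0))
  ok <- c("region", "facility_type")
  if (!length(by) || !all(by %in% ok)) {
    stop_config(sprintf("grouping must be 'overall' or a subset of {%s}",
                        paste(ok, collapse = ", ")))
  }
  by
}

#' Reporting completeness by group and data element
#'
#' For each (group, element), the monthly reporting proportion is the number
#' of facilities in the group reporting the element that month divided by
#' the number reporting it at least once during the year (the per-element
#' eligible set); completeness is 100 times the mean of that proportion over
#' the fiscal months. Equivalently, total reports / (months x eligible
#' facilities). Elements never reported by any facility of a group are
#' omitted and listed in the `never_reported` attribute.
#'
#' Completeness is a presence metric: run it on the uncensored panel —
#' outlier censoring changes values into missing and would otherwise
#' depress it.
#'
#' @param panel a [monthly_panel()].
#' @param registry facility registry supplying the grouping labels.
#' @param by `"overall"`, `"region"`, `"facility_type"`, or
#'   `c("region", "facility_type")`.
#' @param elements element codes to assess (default: full catalogue).
#' @return tibble with the group columns, `element_code`, `eligible_n`,
#'   `n_reports` and `completeness_pct`; attribute `never_reported` holds
#'   the omitted (group, element) pairs.
#' @export
completeness <- function(panel, registry, by = "region",
                         elements = element_catalogue()$code) {
  group_cols <- normalise_grouping(by)
  fy <- panel_fiscal_year(panel)
  x <- panel %>%
    as_tibble() %>%
    filter(element_code %in% elements) %>%
    inner_join(registry %>% select(facility_id, region, facility_type),
               by = "facility_id")
  grid <- registry %>%
    distinct(across(all_of(group_cols))) %>%
    tidyr::crossing(element_code = elements)
  if (nrow(x) == 0) {
    warn("panel has no records for the requested elements; completeness table is empty")
    out <- tibble(element_code = character(0), eligible_n = integer(0),
                  n_reports = integer(0), completeness_pct = numeric(0))
    for (g in rev(group_cols)) out <- bind_cols(tibble(!!g := character(0)), out)
    attr(out, "never_reported") <- grid
    return(out)
  }
  out <- x %>%
    group_by(across(all_of(group_cols)), element_code) %>%
    summarise(eligible_n = n_distinct(facility_id),
              n_reports = n(), .groups = "drop") %>%
    mutate(completeness_pct = 100 * n_reports / (fy$n_months * eligible_n))
  attr(out, "never_reported") <- grid %>%
    anti_join(out, by = c(group_cols, "element_code"))
  out
}

#' Average completeness across elements
#'
#' The per-group summary row: the unweighted mean of the group's per-element
#' completeness values (elements never reported do not enter the mean).
#'
#' @param ct a table from [completeness()].
#' @return tibble with the group columns, `n_elements` and
#'   `avg_completeness_pct`.
#' @export
completeness_summary <- function(ct) {
  group_cols <- setdiff(names(ct),
                        c("element_code", "eligible_n", "n_reports",
                          "completeness_pct"))
  ct %>%
    group_by(across(all_of(group_cols))) %>%
    summarise(n_elements = n(),
              avg_completeness_pct = mean(completeness_pct),
              .groups = "drop")
}

#' Flag extreme positive outliers
#'
#' For every (facility, element) series of reported months, the mean and
#' sample standard deviation (n-1 denominator, candidate month included) are
#' computed over the year; a cell is flagged when its volume exceeds
#' `volume_threshold` clients and its z-score exceeds `z_threshold`. Series
#' with fewer than `min_months` reported months, or with zero spread, yield
#' no flags. Only positive deviations can exceed the threshold, so the
#' screen targets extreme positive outliers.
#'
#' Note the algebraic ceiling: with the candidate included, the largest
#' attainable z in a series of n reported months is (n-1)/sqrt(n), so series
#' with 10 or fewer reported months can never exceed z = 3.
#'
#' @param panel a [monthly_panel()].
#' @param volume_threshold minimum volume for a flaggable cell (default 100,
#'   strict inequality).
#' @param z_threshold z-score threshold (default 3, strict inequality).
#' @param min_months minimum reported months per series (default 3).
#' @return tibble of flags: `facility_id`, `element_code`, `month`, `value`,
#'   `facility_mean`, `facility_sd`, `z`.
#' @export
detect_outliers <- function(panel, volume_threshold = 100, z_threshold = 3,
                            min_months = 3) {
  panel %>%
    as_tibble() %>%
    group_by(facility_id, element_code) %>%
    mutate(n_rep = n(),
           facility_mean = mean(value),
           facility_sd = sd(value)) %>%
    ungroup() %>%
    filter(n_rep >= min_months, facility_sd > 0) %>%
    mutate(z = (value - facility_mean) / facility_sd) %>%
    filter(value > volume_threshold, z > z_threshold) %>%
    select(facility_id, element_code, month, value, facility_mean,
           facility_sd, z)
}

#' Censor flagged outliers
#'
#' Sets exactly the flagged cells to missing (removes the records); all
#' other cells are untouched. The pipeline performs a single
#' detect-then-censor pass: re-running detection on the censored panel may
#' flag new cells because each series' mean and SD change, and no such
#' iteration is performed.
#'
#' @param panel the [monthly_panel()] the flags were computed from.
#' @param flags output of [detect_outliers()].
#' @return the censored panel; attribute `n_censored` records the removal
#'   count.
#' @export
censor_outliers <- function(panel, flags) {
  fy <- panel_fiscal_year(panel)
  src <- attr(panel, "source")
  if (nrow(flags) == 0) {
    out <- panel
    attr(out, "n_censored") <- 0L
    return(out)
  }
  keys <- c("facility_id", "element_code", "month")
  missing <- flags %>% anti_join(as_tibble(panel), by = keys)
  if (nrow(missing)) {
    stop_consistency(sprintf(
      "flag(s) reference cells absent from the panel, first: %s",
      paste(missing$facility_id[1], missing$element_code[1], missing$month[1])
    ))
  }
  kept <- as_tibble(panel) %>% anti_join(flags, by = keys)
  out <- monthly_panel(kept, fiscal_year = fy, source = src)
  attr(out, "n_censored") <- nrow(flags)
  out
}

#' Internal-consistency flags on indicator estimates
#'
#' An indicator whose numerator exceeds its denominator at some aggregation
#' level (percentage > 100) signals an internal-consistency problem — e.g.
#' services delivered outside the visits that define the denominator, or
#' referral inflow at higher tiers.
#'
#' @param estimates output of [compute_indicators()].
#' @return the flagged rows (group columns, `indicator_id`, `name`,
#'   `percentage`).
#' @export
consistency_check <- function(estimates) {
  estimates %>%
    filter(!is.na(percentage), percentage > 100) %>%
    select(any_of(c("region", "facility_type")), indicator_id, name, percentage)
}
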