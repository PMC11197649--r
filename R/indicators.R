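# Annual aggregation and indicator construction: element totals per group,
# the 14 numerator/denominator percentages, cross-region averages, and
# service-volume shares.

#' Annual element totals per group
#'
#' Sums all reported monthly values of each element over the facilities of
#' each group; unreported months contribute zero. Every (group, element)
#' combination present in the registry and catalogue is emitted, zero-filled
#' when nothing was reported.
#'
#' @param panel a [monthly_panel()] (normally after outlier censoring).
#' @param registry facility registry; every panel facility must appear in it.
#' @param by `"overall"`, `"region"`, `"facility_type"` or both.
#' @param elements element codes to total.
#' @return tibble with the group columns, `element_code`, `total`.
#' @export
aggregate_annual <- function(panel, registry, by = "region",
                             elements = element_catalogue()$code) {
  group_cols <- normalise_grouping(by)
  unknown <- setdiff(unique(panel$facility_id), registry$facility_id)
  if (length(unknown)) {
    stop_domain(sprintf("panel facilities absent from the registry: %s",
                        oxford(unknown)))
  }
  x <- panel %>%
    as_tibble() %>%
    filter(element_code %in% elements) %>%
    inner_join(registry %>% select(facility_id, region, facility_type),
               by = "facility_id")
  sums <- x %>%
    group_by(across(all_of(group_cols)), element_code) %>%
    summarise(total = sum(value), .groups = "drop")
  grid <- registry %>%
    distinct(across(all_of(group_cols))) %>%
    tidyr::crossing(element_code = elements)
  if (length(group_cols)) {
    silent <- grid %>%
      distinct(across(all_of(group_cols))) %>%
      anti_join(sums %>% distinct(across(all_of(group_cols))), by = group_cols)
    if (nrow(silent)) {
      warn(sprintf("group(s) with no reporting facilities, totals set to 0: %s",
                   oxford(apply(silent, 1, paste, collapse = "/"))))
    }
  }
  grid %>%
    left_join(sums, by = c(group_cols, "element_code")) %>%
    mutate(total = tidyr::replace_na(total, 0))
}

#' Compute indicator estimates from annual totals
#'
#' Each indicator's percentage is 100 x numerator total / denominator total
#' within the group. A zero denominator yields status `"unavailable"`
#' (never a division error). When the grouping includes `facility_type`,
#' (indicator, type) pairs whose elements the tier does not collect yield
#' status `"not_applicable"` with `NA` sums — distinct from a zero total.
#' Estimates above 100% are marked with `consistency_flag`.
#'
#' @param totals output of [aggregate_annual()].
#' @param catalogue indicator catalogue.
#' @param applicability facility-type applicability map.
#' @return tibble with the group columns, `indicator_id`, `name`,
#'   `numerator_sum`, `denominator_sum`, `percentage` (full precision),
#'   `consistency_flag`, `status`.
#' @export
compute_indicators <- function(totals, catalogue = indicator_catalogue(),
                               applicability = type_applicability()) {
  group_cols <- setdiff(names(totals), c("element_code", "total"))
  est <- if (length(group_cols)) {
    tidyr::crossing(distinct(totals, across(all_of(group_cols))), catalogue)
  } else {
    catalogue
  }
  est <- est %>%
    left_join(totals %>% rename(numerator = element_code, numerator_sum = total),
              by = c(group_cols, "numerator")) %>%
    left_join(totals %>% rename(denominator = element_code,
                                denominator_sum = total),
              by = c(group_cols, "denominator"))
  if ("facility_type" %in% group_cols) {
    app <- applicability %>% filter(applicable) %>% select(-applicable)
    est <- est %>%
      left_join(app %>% mutate(applicable_num = TRUE) %>%
                  rename(numerator = element_code),
                by = c("facility_type", "numerator")) %>%
      left_join(app %>% mutate(applicable_den = TRUE) %>%
                  rename(denominator = element_code),
                by = c("facility_type", "denominator")) %>%
      mutate(applicable = !is.na(applicable_num) & !is.na(applicable_den)) %>%
      select(-applicable_num, -applicable_den)
  } else {
    est$applicable <- TRUE
  }
  est %>%
    mutate(
      status = case_when(
        !applicable ~ "not_applicable",
        is.na(denominator_sum) | denominator_sum == 0 ~ "unavailable",
        TRUE ~ "available"
      ),
      numerator_sum = ifelse(applicable, numerator_sum, NA_real_),
      denominator_sum = ifelse(applicable, denominator_sum, NA_real_),
      percentage = ifelse(status == "available",
                          100 * numerator_sum / denominator_sum, NA_real_),
      consistency_flag = !is.na(percentage) & percentage > 100
    ) %>%
    select(all_of(group_cols), indicator_id, name, numerator_sum,
           denominator_sum, percentage, consistency_flag, status) %>%
    arrange(across(all_of(group_cols)), indicator_id)
}

#' Cross-region average of an indicator table
#'
#' The unweighted arithmetic mean of the unrounded regional percentages
#' (not a pooled ratio, and not a mean of display-rounded values); rounding
#' to one decimal happens only at display time. Regions where the estimate
#' is unavailable are excluded from the mean.
#'
#' @param estimates output of [compute_indicators()] grouped by region.
#' @return tibble with `indicator_id`, `name`, `average_pct`, `n_regions`.
#' @export
regional_average <- function(estimates) {
  if (!"region" %in% names(estimates)) {
    stop_config("regional_average needs estimates grouped by region")
  }
  estimates %>%
    group_by(indicator_id, name) %>%
    summarise(
      average_pct = ifelse(any(status == "available"),
                           mean(percentage[status == "available"]), NA_real_),
      n_regions = sum(status == "available"),
      .groups = "drop"
    ) %>%
    arrange(indicator_id)
}

#' Service-volume shares
#'
#' Share of the total volume of one element (default `xxv`, total outpatient
#' visits) contributed by each group; shares sum to 100% of the grand total.
#'
#' @param panel a [monthly_panel()].
#' @param registry facility registry.
#' @param by grouping columns (default `"facility_type"`).
#' @param element element code to share out.
#' @return tibble with the group columns, `total`, `share_pct`; attribute
#'   `available` is `FALSE` (with zero rows) when the element was never
#'   reported.
#' @export
volume_shares <- function(panel, registry, by = "facility_type",
                          element = "xxv") {
  group_cols <- normalise_grouping(by)
  x <- panel %>% as_tibble() %>% filter(element_code == element)
  if (nrow(x) == 0) {
    warn(sprintf("element %s has no reports; volume shares unavailable", element))
    out <- registry %>%
      distinct(across(all_of(group_cols))) %>%
      filter(FALSE) %>%
      mutate(total = numeric(0), share_pct = numeric(0))
    attr(out, "available") <- FALSE
    return(out)
  }
  totals <- aggregate_annual(panel, registry, by = by, elements = element)
  out <- totals %>%
    select(-element_code) %>%
    mutate(share_pct = 100 * total / sum(total))
  attr(out, "available") <- TRUE
  out
}

#' @rdname volume_shares
#' @param shares a facility-type share table from [volume_shares()].
#' @return `hospital_share()`: the combined public + private hospital share
#'   (percent).
#' @export
hospital_share <- function(shares) {
  if (!"facility_type" %in% names(shares)) {
    stop_config("hospital_share needs shares grouped by facility_type")
  }
  sum(shares$share_pct[shares$facility_type %in% hospital_types()])
}
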