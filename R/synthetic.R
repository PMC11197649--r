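# Synthetic DHIS2 panel generator. Emulates the statistical structure the
# downstream analysis assumes — per-region reporting propensities, the
# no-zero-reporting convention (zeros appear as missing), overdispersed
# count volumes, numerators binomially thinned from their denominators so
# that true indicator ratios are known exactly, and rare multiplicative
# outliers — and returns full ground truth for parameter-recovery tests.

default_facility_counts <- function() {
  tribble(
    ~region,        ~facility_type,     ~n,
    "Addis Ababa",  "health_centre",    10L,
    "Addis Ababa",  "public_hospital",   2L,
    "Addis Ababa",  "private_clinic",   12L,
    "Addis Ababa",  "private_hospital",  2L,
    "Oromia",       "health_post",      40L,
    "Oromia",       "health_centre",    10L,
    "Oromia",       "public_hospital",   2L,
    "Oromia",       "private_clinic",   10L,
    "Oromia",       "private_hospital",  1L,
    "Somali",       "health_post",      14L,
    "Somali",       "health_centre",     4L,
    "Somali",       "public_hospital",   1L,
    "Somali",       "private_clinic",    2L
  )
}

# plausible true indicator ratios (numerator / denominator)
default_indicator_truth <- function() {
  c(`1` = 0.15, `2` = 0.25, `3` = 0.70, `4` = 0.80, `5` = 0.75,
    `6` = 0.80, `7` = 0.92, `8` = 0.93, `9` = 0.45, `10` = 0.85,
    `11` = 0.90, `12` = 0.75, `13` = 0.75, `14` = 0.50)
}

# mean monthly volume per denominator/stand-alone element at a reference
# health centre; facility-type multipliers scale them
default_volume_means <- function() {
  c(ii = 60, iii = 100, ix = 100, xi = 100, xiv = 40, xvi = 40,
    xviii = 30, xx = 50, xxii = 40, xxiv = 250, xxv = 400, xxvi = 80)
}

default_type_multiplier <- function() {
  c(health_post = 0.4, health_centre = 1, public_hospital = 3,
    private_clinic = 0.3, private_hospital = 0.8)
}

#' Configuration of the synthetic panel generator
#'
#' @param facility_counts tibble `(region, facility_type, n)` giving the
#'   registry composition. The default ships three regions and five facility
#'   types in proportions echoing a national registry, scaled to ~110
#'   facilities.
#' @param report_prob probability that a facility-month cell is transmitted.
#'   A scalar, a named vector by region (default: 0.83 / 0.66 / 0.53 for the
#'   urban / agrarian / pastoral region), or a tibble with any of
#'   `region`, `facility_type`, `element_code` plus `prob`.
#' @param volume_mean named vector of mean monthly counts per denominator or
#'   stand-alone element (health-centre reference level); unnamed scalar to
#'   use one mean everywhere.
#' @param type_multiplier named vector scaling volumes by facility type.
#' @param volume_dispersion variance-to-mean ratio of the negative-binomial
#'   monthly volumes (must be >= 1; 1 = Poisson). Default 1.5.
#' @param indicator_truth named vector of true ratios per indicator id.
#'   Values > 1 deliberately synthesise internal-consistency violations.
#' @param zero_prob probability a facility-month has no activity for an
#'   element (a structural zero, which is never reported).
#' @param outlier_rate probability that a reported cell is inflated.
#' @param outlier_scale multiplicative inflation factor (default 50).
#' @param elements,indicators,applicability catalogues (subset `elements`
#'   to generate a smaller panel; indicators lacking either element are
#'   dropped automatically).
#' @param fiscal_year reporting window.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(facility_counts = default_facility_counts(),
                             report_prob = c("Addis Ababa" = 0.83,
                                             "Oromia" = 0.66,
                                             "Somali" = 0.53),
                             volume_mean = default_volume_means(),
                             type_multiplier = default_type_multiplier(),
                             volume_dispersion = 1.5,
                             indicator_truth = default_indicator_truth(),
                             zero_prob = 0.05,
                             outlier_rate = 0.001,
                             outlier_scale = 50,
                             elements = element_catalogue(),
                             indicators = indicator_catalogue(),
                             applicability = type_applicability(),
                             fiscal_year = dhisdash::fiscal_year(),
                             seed = 1L) {
  facility_counts <- as_tibble(facility_counts)
  if (!all(c("region", "facility_type", "n") %in% names(facility_counts))) {
    stop_config("facility_counts needs columns region, facility_type, n")
  }
  if (any(facility_counts$n < 0)) stop_config("facility counts must be >= 0")
  probs_ok <- function(p) all(p >= 0 & p <= 1)
  if (is.data.frame(report_prob)) {
    if (!probs_ok(report_prob$prob)) stop_config("report_prob outside [0,1]")
  } else if (!probs_ok(report_prob)) stop_config("report_prob outside [0,1]")
  if (!probs_ok(zero_prob) || !probs_ok(outlier_rate)) {
    stop_config("zero_prob and outlier_rate must lie in [0,1]")
  }
  if (any(volume_mean <= 0)) stop_config("volume_mean must be > 0")
  if (volume_dispersion < 1) {
    stop_config("volume_dispersion is a variance-to-mean ratio and must be >= 1")
  }
  if (outlier_scale <= 1) stop_config("outlier_scale must be > 1")
  if (any(indicator_truth < 0)) stop_config("indicator_truth must be >= 0")

  # restrict catalogues to the generated element set: indicators need both
  # elements present, the applicability map is intersected
  indicators <- indicators %>%
    filter(numerator %in% elements$code, denominator %in% elements$code)
  applicability <- applicability %>% filter(element_code %in% elements$code)
  # a numerator cannot be applicable where its denominator is not
  bad <- indicators %>%
    left_join(applicability %>% rename(numerator = element_code,
                                       applicable_num = applicable),
              by = "numerator", relationship = "many-to-many") %>%
    left_join(applicability %>% rename(denominator = element_code,
                                       applicable_den = applicable,
                                       facility_type2 = facility_type),
              by = c("denominator", "facility_type" = "facility_type2")) %>%
    filter(applicable_num & !applicable_den)
  if (nrow(bad)) {
    stop_config(sprintf(
      "applicability inconsistency: numerator applicable but denominator not for %s",
      oxford(unique(paste(bad$facility_type, "indicator", bad$indicator_id)))
    ))
  }
  miss_p <- setdiff(as.character(indicators$indicator_id), names(indicator_truth))
  if (length(miss_p)) {
    stop_config(sprintf("indicator_truth missing id(s): %s", oxford(miss_p)))
  }

  structure(
    list(facility_counts = facility_counts, report_prob = report_prob,
         volume_mean = volume_mean, type_multiplier = type_multiplier,
         volume_dispersion = volume_dispersion,
         indicator_truth = indicator_truth, zero_prob = zero_prob,
         outlier_rate = outlier_rate, outlier_scale = outlier_scale,
         elements = elements, indicators = indicators,
         applicability = applicability, fiscal_year = fiscal_year,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# per-row report probability under the three supported shapes
resolve_report_prob <- function(grid, report_prob) {
  if (is.data.frame(report_prob)) {
    keys <- intersect(c("region", "facility_type", "element_code"),
                      names(report_prob))
    if (!length(keys) || !("prob" %in% names(report_prob))) {
      stop_config("tabular report_prob needs a prob column and at least one key column")
    }
    out <- grid %>% left_join(as_tibble(report_prob), by = keys)
    if (anyNA(out$prob)) {
      stop_config("tabular report_prob does not cover every generated cell")
    }
    return(out$prob)
  }
  if (length(report_prob) == 1L && is.null(names(report_prob))) {
    return(rep(unname(report_prob), nrow(grid)))
  }
  p <- report_prob[grid$region]
  if (anyNA(p)) {
    stop_config(sprintf("report_prob has no entry for region(s): %s",
                        oxford(setdiff(unique(grid$region), names(report_prob)))))
  }
  unname(p)
}

# mean volume for a (facility_type, element) pair
resolve_volume_mean <- function(grid, volume_mean, type_multiplier) {
  base <- if (length(volume_mean) == 1L && is.null(names(volume_mean))) {
    rep(unname(volume_mean), nrow(grid))
  } else {
    b <- volume_mean[grid$element_code]
    b[is.na(b)] <- if (is.null(names(volume_mean))) volume_mean[1] else 100
    unname(b)
  }
  mult <- type_multiplier[grid$facility_type]
  mult[is.na(mult)] <- 1
  base * unname(mult)
}

#' Generate a synthetic facility-month panel with ground truth
#'
#' Monthly true counts of denominator and stand-alone elements are drawn
#' from a negative binomial (variance-to-mean ratio
#' `volume_dispersion`), zeroed with probability `zero_prob`. Each
#' indicator's numerator element is drawn `Binomial(denominator count, p)`
#' conditionally on the same facility-month denominator when the true ratio
#' `p <= 1`, and as `round(p * denominator)` when `p > 1` (to synthesise
#' internal-consistency violations). Cells are transmitted with their
#' reporting probability; zeros are never transmitted; reported cells are
#' multiplied by `outlier_scale` with probability `outlier_rate`.
#'
#' @param config a [synthetic_config()].
#' @return list with `panel` (a [monthly_panel()]), `registry`, and `truth`
#'   (class `synthetic_truth`: the full latent cell table with reporting
#'   mask and outlier positions, plus the config).
#' @export
simulate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    fc <- config$facility_counts %>% filter(n > 0)
    registry <- fc %>%
      tidyr::uncount(n) %>%
      mutate(facility_id = sprintf("F%05d", row_number()),
             sector = facility_sector(facility_type)) %>%
      select(facility_id, region, facility_type, sector)

    applicable <- config$applicability %>% filter(applicable)
    grid <- registry %>%
      select(facility_id, region, facility_type) %>%
      inner_join(applicable, by = "facility_type",
                 relationship = "many-to-many") %>%
      select(-applicable) %>%
      tidyr::crossing(month = seq_len(config$fiscal_year$n_months)) %>%
      arrange(facility_id, element_code, month)

    num_map <- config$indicators %>%
      transmute(element_code = numerator, den_code = denominator,
                p = unname(indicator_truth(config)[as.character(indicator_id)]))

    base <- grid %>% anti_join(num_map, by = "element_code")
    nums <- grid %>% inner_join(num_map, by = "element_code")

    # latent volumes for base (denominator / stand-alone) elements
    mu <- resolve_volume_mean(base, config$volume_mean, config$type_multiplier)
    active <- runif(nrow(base)) >= config$zero_prob
    d <- config$volume_dispersion
    draw <- if (d > 1) {
      rnbinom(nrow(base), size = mu / (d - 1), mu = mu)
    } else {
      rpois(nrow(base), mu)
    }
    base$true_value <- as.numeric(active) * draw

    # numerators thinned from their paired denominator cell
    nums <- nums %>%
      left_join(base %>% select(facility_id, element_code, month, true_value) %>%
                  rename(den_code = element_code, den_value = true_value),
                by = c("facility_id", "den_code", "month"))
    if (anyNA(nums$den_value)) {
      stop_config("internal: numerator cell without a generated denominator cell")
    }
    le1 <- nums$p <= 1
    nv <- numeric(nrow(nums))
    nv[le1] <- rbinom(sum(le1), size = nums$den_value[le1], prob = nums$p[le1])
    nv[!le1] <- round_half_up(nums$p[!le1] * nums$den_value[!le1], 0)
    nums$true_value <- nv

    cells <- bind_rows(
      base %>% select(facility_id, region, facility_type, element_code, month,
                      true_value),
      nums %>% select(facility_id, region, facility_type, element_code, month,
                      true_value)
    ) %>% arrange(facility_id, element_code, month)

    cells$reported <- runif(nrow(cells)) < resolve_report_prob(cells, config$report_prob)
    eligible_out <- cells$reported & cells$true_value > 0
    cells$outlier <- eligible_out & runif(nrow(cells)) < config$outlier_rate
    cells$final_value <- ifelse(cells$outlier,
                                cells$true_value * config$outlier_scale,
                                cells$true_value)

    obs <- cells %>% filter(reported, final_value > 0)
    panel <- monthly_panel(
      obs %>% select(facility_id, element_code, month, value = final_value),
      fiscal_year = config$fiscal_year, source = "synthetic"
    )
    truth <- structure(list(cells = cells, config = config),
                       class = "synthetic_truth")
    list(panel = panel, registry = registry, truth = truth)
  })
}

indicator_truth <- function(config) config$indicator_truth

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d latent cells, %d reported, %d outliers injected\n",
              nrow(x$cells), sum(x$cells$reported & x$cells$final_value > 0),
              sum(x$cells$outlier)))
  invisible(x)
}

#' Closed-form summaries of a synthetic truth
#'
#' Computes, directly from the latent cell table (never from the panel),
#' the quantities the pipeline is supposed to recover: per-group true
#' reporting completeness per element, true indicator ratios from the
#' un-inflated latent counts, and the number of injected outliers.
#'
#' @param truth a `synthetic_truth` from [simulate_panel()].
#' @param by grouping columns among `region`, `facility_type`, or
#'   `"overall"`.
#' @return list of tibbles `completeness`, `indicator_truth`, `outliers`.
#' @export
truth_summary <- function(truth, by = "region") {
  stopifnot(inherits(truth, "synthetic_truth"))
  cells <- truth$cells
  group_cols <- if (identical(by, "overall")) character(0) else by
  n_months <- truth$config$fiscal_year$n_months
  cells <- cells %>% mutate(observed = reported & final_value > 0)

  comp <- cells %>%
    group_by(across(all_of(group_cols)), element_code, facility_id) %>%
    summarise(n_obs = sum(observed), .groups = "drop") %>%
    group_by(across(all_of(group_cols)), element_code) %>%
    summarise(eligible_n = sum(n_obs > 0),
              completeness_pct = 100 * sum(n_obs) / (n_months * max(1, sum(n_obs > 0))),
              .groups = "drop") %>%
    filter(eligible_n > 0)

  cat_ind <- truth$config$indicators
  p_true <- purrr::map_dfr(seq_len(nrow(cat_ind)), function(i) {
    num <- cat_ind$numerator[i]; den <- cat_ind$denominator[i]
    cells %>%
      filter(element_code %in% c(num, den)) %>%
      group_by(across(all_of(group_cols))) %>%
      summarise(
        numerator_sum = sum(true_value[element_code == num]),
        denominator_sum = sum(true_value[element_code == den]),
        .groups = "drop"
      ) %>%
      mutate(indicator_id = cat_ind$indicator_id[i],
             true_pct = ifelse(denominator_sum > 0,
                               100 * numerator_sum / denominator_sum, NA_real_))
  })

  outl <- cells %>%
    group_by(across(all_of(group_cols))) %>%
    summarise(n_outliers = sum(outlier), .groups = "drop")

  list(completeness = comp, indicator_truth = p_true, outliers = outl)
}
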