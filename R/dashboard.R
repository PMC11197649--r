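# One-command orchestration: ingest (or simulate) -> restrict to active
# facilities -> outlier screen and censor -> annual aggregation ->
# indicators per grouping -> cross-region averages -> consistency flags ->
# external-validity triangulation, collected into a reproducible bundle.

#' Configure a dashboard run
#'
#' Exactly one input mode must be given: real inputs (`panel` + `registry`,
#' each either a path or an in-memory object) or a [synthetic_config()].
#'
#' @param panel path to a long CSV export, or a [monthly_panel()].
#' @param registry path to a registry CSV, or a registry tibble.
#' @param synthetic a [synthetic_config()]; mutually exclusive with
#'   `panel`/`registry`.
#' @param seed integer; overrides the synthetic config's seed when given.
#' @param fiscal_year reporting window for file ingestion.
#' @param elements,indicators,applicability,references catalogues.
#' @param volume_threshold,z_threshold,min_months outlier-rule parameters,
#'   see [detect_outliers()].
#' @param tolerance external-validity ratio tolerance, see
#'   [assess_validity()].
#' @param duplicates duplicate-key policy for file ingestion.
#' @return a `dashboard_config` list.
#' @export
dashboard_config <- function(panel = NULL, registry = NULL, synthetic = NULL,
                             seed = NULL,
                             fiscal_year = dhisdash::fiscal_year(),
                             elements = element_catalogue(),
                             indicators = indicator_catalogue(elements = elements),
                             applicability = type_applicability(elements = elements),
                             references = reference_ranges(),
                             volume_threshold = 100, z_threshold = 3,
                             min_months = 3, tolerance = 1.5,
                             duplicates = "error") {
  real <- !is.null(panel) || !is.null(registry)
  if (real && !is.null(synthetic)) {
    stop_config("give either real inputs (panel + registry) or a synthetic config, not both")
  }
  if (!real && is.null(synthetic)) {
    stop_config("no input: supply panel + registry, or a synthetic config")
  }
  if (real && (is.null(panel) || is.null(registry))) {
    stop_config("real input mode needs both panel and registry")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    stop_config("synthetic must be a synthetic_config()")
  }
  if (!is.null(synthetic) && !is.null(seed)) synthetic$seed <- as.integer(seed)
  structure(
    list(panel = panel, registry = registry, synthetic = synthetic,
         seed = seed, fiscal_year = fiscal_year, elements = elements,
         indicators = indicators, applicability = applicability,
         references = references, volume_threshold = volume_threshold,
         z_threshold = z_threshold, min_months = min_months,
         tolerance = tolerance, duplicates = duplicates),
    class = "dashboard_config"
  )
}

# fingerprint of the run configuration (input paths or synthetic parameters
# and all rule parameters), stamped on every bundle
dashboard_hash <- function(config) {
  syn <- config$synthetic
  config_hash(list(
    panel = if (is.character(config$panel)) config$panel else "in-memory",
    registry = if (is.character(config$registry)) config$registry else "in-memory",
    synthetic = if (!is.null(syn)) {
      list(seed = syn$seed, zero_prob = syn$zero_prob,
           outlier_rate = syn$outlier_rate, outlier_scale = syn$outlier_scale,
           volume_dispersion = syn$volume_dispersion,
           report_prob = syn$report_prob,
           facility_counts = syn$facility_counts,
           indicator_truth = syn$indicator_truth)
    },
    fiscal_year = config$fiscal_year$codes,
    volume_threshold = config$volume_threshold,
    z_threshold = config$z_threshold, min_months = config$min_months,
    tolerance = config$tolerance
  ))
}

#' Run the full dashboard pipeline
#'
#' Stage order is fixed: ingest (or simulate), restrict the registry to
#' active facilities, assess completeness on the uncensored panel, screen
#' and censor outliers, aggregate annually, compute indicators by region
#' and by region x facility type, average across regions, flag internal
#' consistency, and triangulate against the external references.
#'
#' @param config a [dashboard_config()].
#' @return a `dashboard_bundle`: tables `completeness_region`,
#'   `completeness_summary_region`, `completeness_region_type`,
#'   `outlier_flags`, `dashboard_region`, `regional_averages`,
#'   `dashboard_region_type`, `consistency_flags`, `validity`,
#'   `volume_shares_type`, `volume_shares_region`, plus `run_log` and
#'   `truth` (synthetic runs only).
#' @export
run_dashboard <- function(config) {
  stopifnot(inherits(config, "dashboard_config"))
  truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- simulate_panel(config$synthetic)
    panel <- sim$panel; registry <- sim$registry; truth <- sim$truth
  } else {
    panel <- config$panel
    if (is.character(panel)) {
      panel <- read_long_export(panel, fiscal_year = config$fiscal_year,
                                duplicates = config$duplicates)
    }
    registry <- config$registry
    if (is.character(registry)) registry <- read_facility_registry(registry)
    if (!inherits(panel, "monthly_panel")) {
      panel <- monthly_panel(panel, fiscal_year = config$fiscal_year)
    }
  }

  res <- restrict_to_active(panel, registry, elements = config$elements$code)
  panel <- res$panel; registry <- res$registry

  comp_region <- completeness(panel, registry, by = "region",
                              elements = config$elements$code)
  comp_region_type <- completeness(panel, registry,
                                   by = c("region", "facility_type"),
                                   elements = config$elements$code)

  flags <- detect_outliers(panel, volume_threshold = config$volume_threshold,
                           z_threshold = config$z_threshold,
                           min_months = config$min_months)
  censored <- censor_outliers(panel, flags)

  totals_region <- aggregate_annual(censored, registry, by = "region",
                                    elements = config$elements$code)
  est_region <- compute_indicators(totals_region, config$indicators,
                                   config$applicability)
  averages <- regional_average(est_region)

  totals_type <- suppressWarnings(
    aggregate_annual(censored, registry, by = c("region", "facility_type"),
                     elements = config$elements$code)
  )
  est_type <- compute_indicators(totals_type, config$indicators,
                                 config$applicability)

  cons <- bind_rows(
    consistency_check(est_region),
    consistency_check(est_type)
  )
  validity <- assess_validity(averages, config$references,
                              tolerance = config$tolerance)

  shares_type <- suppressWarnings(volume_shares(censored, registry,
                                                by = "facility_type"))
  shares_region <- suppressWarnings(volume_shares(censored, registry,
                                                  by = "region"))

  run_log <- c(res$log, list(
    records_in = nrow(panel),
    outliers_censored = nrow(flags),
    records_after_censoring = nrow(censored),
    consistency_flags = nrow(cons),
    config_hash = dashboard_hash(config)
  ))

  structure(
    list(completeness_region = comp_region,
         completeness_summary_region = completeness_summary(comp_region),
         completeness_region_type = comp_region_type,
         outlier_flags = flags,
         dashboard_region = est_region,
         regional_averages = averages,
         dashboard_region_type = est_type,
         consistency_flags = cons,
         validity = validity,
         volume_shares_type = shares_type,
         volume_shares_region = shares_region,
         run_log = run_log,
         truth = truth,
         config = config),
    class = "dashboard_bundle"
  )
}

#' @export
print.dashboard_bundle <- function(x, ...) {
  lg <- x$run_log
  cat("<dashboard_bundle>\n")
  cat(sprintf("  facilities: %d listed, %d active (%d dropped); %d facility-months\n",
              lg$n_listed, lg$n_retained, lg$n_dropped, lg$facility_months))
  cat(sprintf("  records: %d in, %d outliers censored, %d analysed\n",
              lg$records_in, lg$outliers_censored, lg$records_after_censoring))
  cat(sprintf("  consistency flags: %d | validity: %s\n",
              lg$consistency_flags,
              paste(sprintf("%d %s", table(x$validity$verdict),
                            names(table(x$validity$verdict))), collapse = ", ")))
  cat(sprintf("  config hash: %s\n", lg$config_hash))
  invisible(x)
}

#' Write a dashboard bundle to disk
#'
#' Writes every table as CSV (canonical, percentages at one decimal) and a
#' JSON machine twin of the whole bundle, plus the run log with the config
#' hash. File contents are deterministic for a fixed config and seed.
#'
#' @param bundle a `dashboard_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "dashboard_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("completeness_region", "completeness_summary_region",
              "completeness_region_type", "outlier_flags",
              "dashboard_region", "regional_averages",
              "dashboard_region_type", "consistency_flags", "validity",
              "volume_shares_type", "volume_shares_region")
  for (tb in tables) {
    write_table(bundle[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  machine <- c(lapply(setNames(tables, tables), function(tb) bundle[[tb]]),
               list(run_log = bundle$run_log))
  jsonlite::write_json(machine, file.path(dir, "bundle.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  jsonlite::write_json(bundle$run_log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Wide display table of the regional dashboard
#'
#' Formats the regional indicator estimates the way the dashboard is read:
#' one row per indicator, one column per region (one-decimal percentages,
#' `>100%` cells marked with `*`), the cross-region average, and the
#' external-validity verdict.
#'
#' @param bundle a `dashboard_bundle`.
#' @return a wide tibble of formatted strings.
#' @export
format_regional_table <- function(bundle) {
  est <- bundle$dashboard_region %>%
    mutate(cell = paste0(fmt_pct(percentage),
                         ifelse(consistency_flag, "*", ""))) %>%
    select(indicator_id, name, region, cell) %>%
    tidyr::pivot_wider(names_from = region, values_from = cell)
  avg <- bundle$regional_averages %>%
    transmute(indicator_id, average = fmt_pct(average_pct))
  val <- bundle$validity %>%
    transmute(indicator_id,
              external = ifelse(is.na(low), "NA",
                                ifelse(low == high, fmt_pct(low),
                                       paste0(fmt_pct(low), "-", fmt_pct(high)))),
              verdict)
  est %>% left_join(avg, by = "indicator_id") %>% left_join(val, by = "indicator_id")
}
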