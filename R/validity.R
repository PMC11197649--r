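# External-validity triangulation: compare each indicator's cross-region
# average against an external reference value or range and classify it.

#' Triangulate indicator averages against external references
#'
#' Each computed average is compared to its reference interval by a
#' ratio-to-nearest-bound rule: the ratio is 1 when the value lies inside
#' `[low, high]`, `computed/low` (< 1) when below, and `computed/high`
#' (> 1) when above. The verdict is `"acceptable"` when the ratio lies in
#' `[1/tolerance, tolerance]`, `"poor"` otherwise, and `"unassessed"` when
#' no reference is configured or the average is unavailable. The default
#' tolerance of 1.5 means an indicator may run up to 50% above, or down to
#' two-thirds of, its nearest reference bound.
#'
#' @param averages table with `indicator_id` and `average_pct` (e.g. from
#'   [regional_average()]).
#' @param references a [reference_ranges()] table.
#' @param tolerance ratio tolerance, > 1 (default 1.5).
#' @return tibble with `indicator_id`, `name` (if present), `computed`,
#'   `low`, `high`, `source`, `ratio`, `verdict`.
#' @export
assess_validity <- function(averages, references = reference_ranges(),
                            tolerance = 1.5) {
  if (!is.numeric(tolerance) || tolerance <= 1) {
    stop_config("tolerance must be a ratio greater than 1")
  }
  x <- averages %>%
    rename(computed = average_pct) %>%
    left_join(references, by = "indicator_id") %>%
    mutate(
      ratio = case_when(
        is.na(computed) | is.na(low) ~ NA_real_,
        computed >= low & computed <= high ~ 1,
        computed < low ~ computed / low,
        TRUE ~ computed / high
      ),
      verdict = case_when(
        is.na(ratio) ~ "unassessed",
        ratio >= 1 / tolerance & ratio <= tolerance ~ "acceptable",
        TRUE ~ "poor"
      )
    )
  x %>% select(any_of(c("indicator_id", "name")), computed, low, high,
               source, ratio, verdict)
}
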