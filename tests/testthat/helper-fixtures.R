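# Small programmatic fixtures shared across the suite.

toy_registry <- function(ids, regions = "Oromia", types = "health_centre") {
  facility_registry(tibble::tibble(
    facility_id = ids,
    region = rep_len(regions, length(ids)),
    facility_type = rep_len(types, length(ids))
  ))
}

# panel from one facility-element monthly series (months = seq_along(values))
series_panel <- function(values, facility = "F1", element = "iii",
                         months = seq_along(values)) {
  monthly_panel(tibble::tibble(
    facility_id = facility, element_code = element,
    month = months, value = values
  ))
}

# panel built from explicit (facility, element, month, value) rows
rows_panel <- function(...) {
  monthly_panel(tibble::tibble(...))
}

# independent brute-force oracle for the outlier screen: plain loops,
# mean()/sd() on each series, no dplyr grouping
brute_force_outliers <- function(panel, volume_threshold = 100,
                                 z_threshold = 3, min_months = 3) {
  df <- as.data.frame(panel)
  out <- list()
  for (f in unique(df$facility_id)) {
    for (e in unique(df$element_code[df$facility_id == f])) {
      s <- df[df$facility_id == f & df$element_code == e, , drop = FALSE]
      if (nrow(s) < min_months) next
      m <- mean(s$value); sdev <- sd(s$value)
      if (is.na(sdev) || sdev == 0) next
      for (i in seq_len(nrow(s))) {
        zi <- (s$value[i] - m) / sdev
        if (s$value[i] > volume_threshold && zi > z_threshold) {
          out[[length(out) + 1]] <- data.frame(
            facility_id = f, element_code = e, month = s$month[i],
            value = s$value[i], facility_mean = m, facility_sd = sdev, z = zi
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(facility_id = character(0), element_code = character(0),
                          month = integer(0), value = numeric(0),
                          facility_mean = numeric(0), facility_sd = numeric(0),
                          z = numeric(0)))
  }
  tibble::as_tibble(do.call(rbind, out))
}

# a one-region, one-type synthetic config over a subset of elements
quick_config <- function(n = 50, elements = c("iii", "ix"), seed = 1, ...) {
  el <- element_catalogue()
  synthetic_config(
    facility_counts = tibble::tibble(region = "Oromia",
                                     facility_type = "health_centre",
                                     n = as.integer(n)),
    elements = el[el$code %in% elements, ],
    seed = seed, ...
  )
}

# printed regional dashboard percentages (one decimal) and averages used as
# the whole-table regression target
published_regional_pct <- function() {
  tibble::tribble(
    ~indicator_id, ~`Addis Ababa`, ~Oromia, ~Somali, ~average,
    1L,  15.2,  12.7,   4.1, 10.7,
    2L,  23.5,  22.1,  19.3, 21.7,
    3L,  87.3,  70.5,  63.5, 73.8,
    4L,  98.2,  79.9,  46.8, 75.0,
    5L,  91.1,  71.1,  24.1, 62.1,
    6L,  80.0, 113.6,  71.5, 88.4,
    7L,  98.3,  94.8,  88.9, 94.0,
    8L,  99.9,  94.5,  90.1, 94.8,
    9L,  50.0,  46.4,  26.9, 41.1,
    10L, 91.8,  89.3,  81.9, 87.7,
    11L, 93.6,  96.9,  88.1, 92.9,
    12L, 71.4,  80.5,  80.2, 77.4,
    13L, 71.4,  80.7,  80.8, 77.6,
    14L, 41.5,  64.2,  51.8, 52.5
  )
}
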