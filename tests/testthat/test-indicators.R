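test_that("annual totals sum reported months, treating missing months as zero", {
  panel <- rows_panel(facility_id = "F1", element_code = "iii",
                      month = c(1L, 3L), value = c(10, 20))
  tot <- aggregate_annual(panel, toy_registry("F1"), by = "region",
                          elements = "iii")
  expect_equal(tot$total, 30)
})

test_that("totals error on unknown facilities and warn on silent groups", {
  panel <- rows_panel(facility_id = "GHOST", element_code = "iii",
                      month = 1L, value = 5)
  expect_error(aggregate_annual(panel, toy_registry("F1"), by = "region"),
               "GHOST", class = "dhisdash_domain_error")

  p2 <- rows_panel(facility_id = "F1", element_code = "iii", month = 1L, value = 5)
  reg <- toy_registry(c("F1", "F2"), regions = c("Oromia", "Somali"))
  expect_warning(tot <- aggregate_annual(p2, reg, by = "region", elements = "iii"),
                 "Somali")
  expect_equal(tot$total[tot$region == "Somali"], 0)
})

test_that("group totals decompose: partitions sum to the overall total", {
  sim <- simulate_panel(synthetic_config(seed = 14))
  overall <- aggregate_annual(sim$panel, sim$registry, by = "overall")
  by_region <- aggregate_annual(sim$panel, sim$registry, by = "region")
  by_both <- suppressWarnings(
    aggregate_annual(sim$panel, sim$registry, by = c("region", "facility_type")))
  for (e in unique(overall$element_code)) {
    tot <- overall$total[overall$element_code == e]
    expect_equal(sum(by_region$total[by_region$element_code == e]), tot)
    expect_equal(sum(by_both$total[by_both$element_code == e]), tot)
  }
})

test_that("indicator percentages, zero cases and unavailability are handled", {
  tot <- tibble::tibble(region = "Addis Ababa",
                        element_code = c("i", "ii"), total = c(0, 10))
  est <- compute_indicators(tot)
  e1 <- est[est$indicator_id == 1, ]
  expect_equal(e1$percentage, 0)
  expect_equal(e1$status, "available")
  # zero denominator -> unavailable, never a division error
  e3 <- est[est$indicator_id == 3, ]
  expect_equal(e3$status, "unavailable")
  expect_true(is.na(e3$percentage))
})

test_that("published regional counts reproduce the printed percentage cells", {
  tot <- dplyr::rename(efy2015_regional_totals(), total = value)
  est <- compute_indicators(tot)
  addis <- est[est$region == "Addis Ababa", ]
  expect_equal(addis$numerator_sum[addis$indicator_id == 1], 23295)
  expect_equal(addis$denominator_sum[addis$indicator_id == 1], 153626)
  expect_equal(round_half_up(addis$percentage[addis$indicator_id == 1]), 15.2)
  somali <- est[est$region == "Somali", ]
  expect_equal(round_half_up(somali$percentage[somali$indicator_id == 5]), 24.1)
})

test_that("facility-type estimates honour the applicability NA semantics", {
  tot <- tibble::tibble(region = "Oromia", facility_type = "health_post",
                        element_code = c("iii", "iv", "xiv", "xiii"),
                        total = c(100, 25, 0, 0))
  est <- compute_indicators(tot)
  # timely ANC applies at health posts
  expect_equal(est$status[est$indicator_id == 2], "available")
  expect_equal(est$percentage[est$indicator_id == 2], 25)
  # ART retention does not: NA, distinct from a zero total
  expect_equal(est$status[est$indicator_id == 9], "not_applicable")
  expect_true(is.na(est$numerator_sum[est$indicator_id == 9]))
})

test_that("regional averages use unrounded unweighted means, permutation-invariant", {
  mk <- function(pcts, ids = 1L) tibble::tibble(
    region = c("A", "B", "C"), indicator_id = ids, name = "x",
    numerator_sum = 1, denominator_sum = 1, percentage = pcts,
    consistency_flag = FALSE, status = "available")
  avg <- regional_average(mk(c(15.163, 12.741, 4.078)))
  expect_equal(round_half_up(avg$average_pct), 10.7)
  # the discriminating case: mean of unrounded 23.548/22.108/19.322 is 21.7,
  # a mean of display-rounded values would give 21.6
  avg2 <- regional_average(mk(c(23.548, 22.108, 19.322)))
  expect_equal(round_half_up(avg2$average_pct), 21.7)
  expect_false(isTRUE(all.equal(round_half_up(mean(c(23.5, 22.1, 19.3))), 21.7)))
  # permutation invariance and single-region identity
  est <- mk(c(50, 60, 70))
  expect_equal(regional_average(est)$average_pct,
               regional_average(est[c(3, 1, 2), ])$average_pct)
  single <- est[1, ]
  expect_equal(regional_average(single)$average_pct, 50)
})

test_that("indicator estimates recover the generator's true ratio", {
  cfg <- quick_config(n = 2000, elements = c("iii", "iv"), seed = 5,
                      report_prob = 1, zero_prob = 0, outlier_rate = 0)
  sim <- simulate_panel(cfg)
  tot <- aggregate_annual(sim$panel, sim$registry, by = "overall",
                          elements = c("iii", "iv"))
  est <- compute_indicators(tot, catalogue = cfg$indicators)
  p <- unname(cfg$indicator_truth["2"])
  D <- est$denominator_sum
  se <- 100 * sqrt(p * (1 - p) / D)
  expect_lt(abs(est$percentage - 100 * p), 3 * se)
})

test_that("volume shares sum to 100 and hospitals combine public and private", {
  panel <- rows_panel(
    facility_id = c("HP", "HC", "PUB", "PC", "PVH"),
    element_code = "xxv", month = 1L,
    value = c(700, 200, 80, 15, 5)
  )
  reg <- toy_registry(c("HP", "HC", "PUB", "PC", "PVH"),
                      types = c("health_post", "health_centre",
                                "public_hospital", "private_clinic",
                                "private_hospital"))
  sh <- volume_shares(panel, reg)
  expect_equal(sum(sh$share_pct), 100)
  expect_equal(hospital_share(sh), 8.5)
  # single facility type -> 100%
  one <- volume_shares(series_panel(rep(10, 3), element = "xxv"),
                       toy_registry("F1"))
  expect_equal(one$share_pct[one$facility_type == "health_centre"], 100)
  # absent element -> explicit unavailable result
  expect_warning(none <- volume_shares(series_panel(rep(10, 3)), toy_registry("F1")),
                 "unavailable")
  expect_equal(nrow(none), 0)
  expect_false(attr(none, "available"))
})
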