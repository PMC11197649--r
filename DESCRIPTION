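Package: dhisdash
Title: Primary Care Performance Dashboards from Routine DHIS2 Facility Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns routine health-facility reports exported from DHIS2
    (monthly facility-level counts of service-delivery data elements) into a
    primary care performance dashboard. Implements reporting-completeness
    metrics on facility-month panels, screening and censoring of extreme
    positive outliers by a facility-level 3-standard-deviation rule, internal
    consistency checks on numerator/denominator pairs, construction of 14
    performance indicators from 26 data elements with regional and
    facility-type disaggregation, service-volume shares, and triangulation of
    computed indicators against external reference estimates. Ships a
    synthetic DHIS2 panel generator with full ground truth (reporting masks,
    latent counts, injected outliers) so that every pipeline stage can be
    validated by parameter recovery without access to a national extract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
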