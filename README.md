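# dhisdash

Primary care performance dashboards from routine DHIS2 facility reports.

National health-management information systems (DHIS2) collect monthly
aggregate counts of service-delivery data elements from every health
facility. This package turns a long facility-month export of such counts
— together with a facility registry — into a primary care performance
dashboard, with the data-quality assessment that has to come first:

* **Reporting completeness** per element and group: the mean, over the 12
  fiscal months, of the share of facilities reporting among those reporting
  the element at least once in the year.
* **Extreme positive outlier screening**: a cell is flagged when its volume
  exceeds 100 clients and lies more than 3 sample standard deviations above
  its facility–element series mean; flagged cells are censored to missing
  in a single pass.
* **Internal consistency**: indicator cells above 100% (numerator exceeds
  denominator at that aggregation level) are flagged.
* **Indicators**: 14 performance indicators from 26 data elements, each
  `100 × Σ numerator / Σ denominator` over the fiscal year, disaggregated
  overall, by region, by facility type, or region × type, with
  not-applicable (NA) semantics for elements a tier does not collect and
  cross-region averages taken as unweighted means of unrounded regional
  percentages.
* **External validity**: each indicator average is triangulated against a
  configured reference value or range (DHS/SPA surveys, ministry reports,
  WHO/UNAIDS) by a ratio-to-nearest-bound rule with tolerance 1.5.
* **Synthetic data**: a generator of facility-month panels with full
  ground truth (reporting masks, latent counts, binomially thinned
  numerators so true indicator ratios are exact, injected ×50 outliers),
  used by the test suite for parameter recovery.

Everything domain-specific — element and indicator catalogues, the
facility-type applicability matrix, external reference ranges — ships as
editable YAML under `inst/extdata/`, so adapting the dashboard to another
DHIS2 configuration is a data change.

## Worked example

The package bundles the published Ethiopian Fiscal Year 2015 (July 2022 –
June 2023) regional annual totals of the 24 indicator elements. Pushing
them through the full pipeline reproduces the regional dashboard:

```r
library(dhisdash)

tp <- totals_to_panel(efy2015_regional_totals())
b  <- run_dashboard(dashboard_config(panel = tp$panel, registry = tp$registry))
format_regional_table(b)
```

```
   indicator_id name                                             Addis Ababa Oromia Somali average external  verdict
1   1           Immediate postpartum contraceptive acceptance    15.2        12.7   4.1    10.7    8.0       acceptable
2   2           Women receiving timely antenatal care            23.5        22.1   19.3   21.7    22.0-37.7 acceptable
3   3           Women retained to fourth antenatal care visit    87.3        70.5   63.5   73.8    58.0-79.0 acceptable
4   4           Syphilis testing coverage in antenatal care      98.2        79.9   46.8   75.0    65.0-74.0 acceptable
5   5           HIV testing coverage in antenatal care           91.1        71.1   24.1   62.1    59.0      acceptable
6   6           Iron and folic acid provision                    80.0        113.6* 71.5   88.4    67.0-77.0 acceptable
7   7           Retention to third pentavalent vaccine dose      98.3        94.8   88.9   94.0    80.3      acceptable
8   8           Retention to second rotavirus vaccine dose       99.9        94.5   90.1   94.8    92.0      acceptable
9   9           People on ART 12 months after initiation         50.0        46.4   26.9   41.1    70.7-76.8 poor
10 10           Viral load suppression                           91.8        89.3   81.9   87.7    81.0-96.4 acceptable
11 11           Tuberculosis treatment success                   93.6        96.9   88.1   92.9    86.0      acceptable
12 12           Patients with hypertension control               71.4        80.5   80.2   77.4    37.5      poor
13 13           Patients with diabetes control                   71.4        80.7   80.8   77.6    34.4      poor
14 14           Patient encounters resulting in antibiotic prescription 41.5 64.2  51.8   52.5    60.0      acceptable
```

Reading the output: each regional column is the annual numerator total over
the annual denominator total, displayed half-up to one decimal. The `*` on
Oromia's iron–folic acid cell (113.6) marks an internal-consistency flag —
more women received supplements than attended a first antenatal visit, so
supplements are evidently delivered outside those visits. The `average`
column is the unweighted mean of the three unrounded regional percentages
(21.7 for timely antenatal care — a mean of the rounded cells would give
21.6). The `verdict` column compares each average with its external
reference by ratio-to-nearest-bound at tolerance 1.5: 11 indicators are
externally consistent, while 12-month ART retention (41.1 vs 70.7–76.8,
ratio 0.58) and hypertension/diabetes control (77.4 vs 37.5 and 77.6 vs
34.4, ratios above 2) have poor external validity.

A fully synthetic run, with ground truth for every stage:

```r
cfg <- synthetic_config(seed = 7)         # ~110 facilities, 3 regions, 5 types
b   <- run_dashboard(dashboard_config(synthetic = cfg))
b
#> <dashboard_bundle>
#>   facilities: 110 listed, 110 active (0 dropped); 1320 facility-months
#>   records: 15905 in, 5 outliers censored, 15900 analysed
#>   consistency flags: 25 | validity: 10 acceptable, 4 poor
#>   config hash: 5a1a7ab4
write_bundle(b, "out/")                   # CSVs + JSON twin + run log
truth_summary(b$truth)                    # recovery targets from the latent cells
```

A thin command-line wrapper over these functions is installed at
`inst/cli/dashboard.R` (subcommands `simulate`, `quality`, `indicators`,
`validity`, `run`).

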