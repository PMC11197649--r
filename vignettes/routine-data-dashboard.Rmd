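---
title: "Methods: from routine DHIS2 facility reports to a primary care dashboard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from routine DHIS2 facility reports to a primary care dashboard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhisdash)
```

## The problem and the data model

National health-management information systems such as DHIS2 collect, from
every health facility, monthly aggregate counts of service-delivery *data
elements* — first antenatal care visits, third pentavalent vaccine doses,
people initiated on antiretroviral therapy (ART), and so on. These routine
data are reported by all facility types at monthly cadence, which makes them
an attractive alternative to infrequent household surveys for monitoring
primary care performance — provided their quality is assessed first.

dhisdash works on a long *facility-month panel*: one row per reported
(facility, element, month) cell with a non-negative integer count, within a
configurable 12-month fiscal window (default July 2022–June 2023, the
Ethiopian Fiscal Year 2015). Two semantics of the platform drive the whole
design:

* **Zeros are not transmitted.** A facility-month with no activity for an
  element appears as a missing cell, indistinguishable in the export from a
  failure to report. Absent keys therefore mean "not reported", and a blank
  value cell on ingestion is dropped rather than read as zero.
* **Counts, not coverage.** All indicators are ratios of two reported
  counts aggregated over the year, never counts over estimated catchment
  populations, whose denominators are notoriously unreliable.

A facility registry (id, region, facility type) supplies the two
disaggregation axes. The sector (public/private) is derived from the type.
Facilities listed in the registry that report none of the 26 catalogue
elements all year are dropped before analysis (`restrict_to_active()`); the
run log books the retained-facility and facility-month counts.

## Data-quality stages

### Reporting completeness

For each group and element, monthly completeness is the share of facilities
reporting the element that month among those reporting it *at least once in
the year* (the per-element eligible set), and annual completeness is the
mean over the twelve months — equivalently, reports / (12 × eligible
facilities). The per-element denominator mirrors how completeness tables
are read element-by-element; a single "any-element" denominator would mix
tiers that do not collect an element at all. Elements never reported in a
group are omitted from the table and listed separately rather than shown as
0%. Because the platform drops zeros, low completeness confounds true
non-reporting with months of genuinely no activity; since the dashboard
aggregates over twelve months, only true failure-to-report biases the
indicator totals. Completeness is computed on the *uncensored* panel:
outlier censoring converts values to missing and would otherwise depress a
presence metric.

### Extreme positive outliers

Unit or transcription errors occasionally inflate a monthly count by orders
of magnitude and would dominate annual sums. Each (facility, element)
series of reported months is screened: a cell is flagged when its volume
exceeds 100 clients and lies more than 3 sample standard deviations above
the series mean. Implementation choices, stated because the rule is usually
quoted without them:

* mean and SD include the candidate month (no leave-one-out), with the
  n−1 sample SD;
* at least 3 reported months are required, and a zero-SD series yields no
  flags;
* the >100 filter decides which cells are *flaggable*, not which months
  enter the mean/SD;
* screening is per element — no pooling across elements within a facility;
* exactly one detect-then-censor pass is run. Re-screening the censored
  panel could flag new cells (the series moments change); no such
  iteration is performed.

A useful algebraic fact: with the candidate included, the largest z
attainable in a series of *n* points is (n−1)/√n, which first exceeds 3 at
n = 11. Series with ten or fewer reported months therefore can never be
flagged under this rule — a structural insensitivity of the published
screen on incomplete series, documented here rather than "fixed". Flagged
cells are set to missing and the censoring count is logged.

### Internal consistency

After aggregation, any indicator whose numerator exceeds its denominator at
some grouping level (percentage > 100) is flagged. Such cells are kept in
the tables — and in cross-region averages — but marked, since they usually
reveal a definitional mismatch (e.g. iron–folic acid supplements delivered
outside the antenatal visits that define the denominator, or referral
inflow at hospitals) rather than a computational error.

### External validity

Each indicator's cross-region average is triangulated against a reference
value or range from independent sources (DHS/SPA surveys, ministry annual
reports, WHO/UNAIDS estimates), shipped as editable YAML. The comparison is
a *ratio to the nearest bound*: 1 inside the interval, computed/low below,
computed/high above; the verdict is acceptable when the ratio lies within
[1/tolerance, tolerance]. Published assessments of this kind are
qualitative; the ratio rule with default tolerance 1.5 is this package's
explicit formalisation of "closely aligned", chosen a priori as "within
50% of the nearest bound" — generous enough that survey-vs-routine
denominator differences do not dominate, strict enough to catch
multiple-fold disagreement. The tolerance is a configuration knob, not a
fitted constant.

## Indicators and aggregation

The 26-element and 14-indicator catalogues are data (YAML), not code. Each
indicator is 100 × (annual numerator total / annual denominator total)
within a group; missing months contribute zero to sums. A zero or absent
denominator gives an "unavailable" estimate, never a division error. When
grouping by facility type, (indicator, type) pairs outside the
applicability map — e.g. ART retention at health posts, which do not run
ART — are "not applicable" (NA), deliberately distinct from a zero total.

Cross-region averages are *unweighted arithmetic means of the unrounded
regional percentages* — a region's performance counts equally regardless of
its volume, and rounding happens once, at display. Display rounding is
half-up to one decimal (`round_half_up()`), the convention of the published
tables; full precision is retained internally. Service-volume shares divide
one element's total (default: total outpatient visits) across facility
types or regions; the hospital share sums the public and private hospital
rows.

## The synthetic generator

`simulate_panel()` generates panels with the statistical structure the
analysis assumes, plus complete ground truth, so every stage is testable by
parameter recovery without any national extract. Per facility × applicable
element × month:

* **Volumes.** Denominator and stand-alone elements draw a negative
  binomial with mean μ (per element, scaled by a facility-type multiplier)
  and variance-to-mean ratio *d* (default 1.5; *d* = 1 is the Poisson
  limit). The ratio parameterisation keeps facility-level spread
  proportional to volume at every tier, and at *d* = 1.5 gives modest
  overdispersion under which the 3-SD screen is informative; with heavier
  within-facility dispersion the (n−1)/√n ceiling above makes any
  mean/SD screen blind, which is a property of the rule, not of the
  generator.
* **Zero months.** With probability `zero_prob` (default 0.05) a
  facility-month has no activity; zero cells are never transmitted,
  reproducing the missing-zero semantics.
* **Numerators by binomial thinning.** Each indicator's numerator is drawn
  Binomial(denominator count, p) on the same facility-month, so the true
  ratio is exactly p and recovery tests are well-posed. Setting p > 1
  (then numerator = round(p × denominator)) deliberately manufactures
  internal-consistency violations.
* **Reporting.** Cells are transmitted with a reporting propensity
  (scalar, per region — defaults 0.83/0.66/0.53 for the urban, agrarian
  and pastoral regions, echoing the strong regional completeness gradient
  of real extracts — or any (region, type, element) table).
* **Outliers.** Reported cells are multiplied by `outlier_scale`
  (default 50) with probability `outlier_rate` (default 0.001);
  multiplicative inflation guarantees realistic outliers clear the
  >100-client eligibility filter at the default volume means.

The default registry ships the three study regions and five facility types
in proportions echoing a national registry, scaled to ~110 facilities so a
full default run takes about a second. What the generator does **not**
emulate: seasonality, quarterly batch-reporting (e.g. tuberculosis
programmes transitioning from quarterly cadence), spatial correlation,
reporting propensities that depend on volume, and negatively biased (too
small) erroneous counts. Recovery tests therefore validate the arithmetic
and the estimators under the stated model, not the realism of any
particular national extract.

Determinism: one seed drives registry construction and all draws; identical
config + seed gives byte-identical panels, truth tables and written
bundles.

## Problem sizes and numerical choices

The test suite exercises hand-enumerable fixtures (3-facility completeness,
a 12-month series with one planted spike where mean 842.5 and z ≈ 3.18 are
checked by hand) and recovery runs at 1 000–4 200 facilities with 1–2
elements, where Monte-Carlo standard errors are small enough for 3-SE
assertions; these sizes keep the whole suite under a minute while the
binomial-thinning construction makes the targets exact. The outlier
detector is verified against a brute-force loop oracle on random panels of
up to 50 facilities. The published EFY-2015 regional totals are pushed
through the pipeline as one-facility-per-region month-1 lumps, which
reproduces every printed percentage and average cell at one-decimal
half-up rounding — including the cross-region average that discriminates
unrounded from rounded averaging (21.7 vs 21.6 for timely antenatal care).

Degenerate inputs are defined, not exceptional: empty panels give empty
completeness tables with a warning; zero denominators give "unavailable";
missing references give "unassessed"; a flag referencing an absent cell is
a consistency error; duplicate export keys follow a configurable policy
(error by default, sum or last-wins selectable, since real exports do
contain duplicates).

## Known limitations

* Quarterly-aggregated reporting is read at face value as monthly; annual
  totals are unaffected but monthly completeness of such programmes is
  understated.
* The 3-SD screen cannot flag series with ≤10 reported months (ceiling
  argument above) and only targets extreme *positive* outliers.
* The external-validity rule is a formalisation; different tolerances give
  different acceptable/poor splits, and references mix survey years.
* Facility-type estimates can be biased by patients moving between tiers
  during the year (referral inflow shows up as >100% retention at
  hospitals); flags surface this but nothing corrects it.
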