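# External reference values/ranges (percent) for triangulating each
# indicator's cross-region average. A point estimate has low == high.
references:
  - indicator_id: 1
    low: 8.0
    high: 8.0
    source: ministry annual performance report
  - indicator_id: 2
    low: 22.0
    high: 37.7
    source: DHS / ministry annual performance report
  - indicator_id: 3
    low: 58.0
    high: 79.0
    source: DHS / ministry annual performance report
  - indicator_id: 4
    low: 65.0
    high: 74.0
    source: SPA survey / ministry annual performance report
  - indicator_id: 5
    low: 59.0
    high: 59.0
    source: DHS
  - indicator_id: 6
    low: 67.0
    high: 77.0
    source: DHS / ministry annual performance report
  - indicator_id: 7
    low: 80.3
    high: 80.3
    source: Mini DHS
  - indicator_id: 8
    low: 92.0
    high: 92.0
    source: Mini DHS
  - indicator_id: 9
    low: 70.7
    high: 76.8
    source: systematic reviews of ART retention cohorts
  - indicator_id: 10
    low: 81.0
    high: 96.4
    source: ministry annual performance report / UNAIDS
  - indicator_id: 11
    low: 86.0
    high: 86.0
    source: WHO global tuberculosis report
  - indicator_id: 12
    low: 37.5
    high: 37.5
    source: WHO global report on hypertension
  - indicator_id: 13
    low: 34.4
    high: 34.4
    source: systematic review of glycaemic control
  - indicator_id: 14
    low: 60.0
    high: 60.0
    source: published outpatient antibiotic prescribing estimate
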