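# Performance indicators: percentage = 100 * numerator element / denominator
# element, aggregated annually within a group of facilities.
indicators:
  - indicator_id: 1
    name: Immediate postpartum contraceptive acceptance
    numerator: i
    denominator: ii
    performance_domain: counselling effectiveness
  - indicator_id: 2
    name: Women receiving timely antenatal care
    numerator: iv
    denominator: iii
    performance_domain: timely care
  - indicator_id: 3
    name: Women retained to fourth antenatal care visit
    numerator: v
    denominator: iii
    performance_domain: care continuity
  - indicator_id: 4
    name: Syphilis testing coverage in antenatal care
    numerator: vi
    denominator: iii
    performance_domain: appropriate care
  - indicator_id: 5
    name: HIV testing coverage in antenatal care
    numerator: vii
    denominator: iii
    performance_domain: appropriate care
  - indicator_id: 6
    name: Iron and folic acid provision
    numerator: viii
    denominator: iii
    performance_domain: appropriate care
  - indicator_id: 7
    name: Retention to third pentavalent vaccine dose
    numerator: x
    denominator: ix
    performance_domain: care continuity
  - indicator_id: 8
    name: Retention to second rotavirus vaccine dose
    numerator: xii
    denominator: xi
    performance_domain: care continuity
  - indicator_id: 9
    name: People on ART 12 months after initiation
    numerator: xiii
    denominator: xiv
    performance_domain: care continuity
  - indicator_id: 10
    name: Viral load suppression
    numerator: xv
    denominator: xvi
    performance_domain: treatment effectiveness
  - indicator_id: 11
    name: Tuberculosis treatment success
    numerator: xvii
    denominator: xviii
    performance_domain: treatment effectiveness
  - indicator_id: 12
    name: Patients with hypertension control
    numerator: xix
    denominator: xx
    performance_domain: treatment effectiveness
  - indicator_id: 13
    name: Patients with diabetes control
    numerator: xxi
    denominator: xxii
    performance_domain: treatment effectiveness
  - indicator_id: 14
    name: Patient encounters resulting in antibiotic prescription
    numerator: xxiii
    denominator: xxiv
    performance_domain: safety
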