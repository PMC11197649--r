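# Monthly data elements reported by health facilities (codes i-xxvi).
elements:
  - code: i
    name: Immediate postpartum contraceptive acceptors
    programme_area: reproductive health
  - code: ii
    name: Births attended by skilled health personnel
    programme_area: reproductive health
  - code: iii
    name: Women attending first antenatal care visit
    programme_area: antenatal care
  - code: iv
    name: First antenatal care visits in the first trimester
    programme_area: antenatal care
  - code: v
    name: Pregnant women attending four antenatal care visits
    programme_area: antenatal care
  - code: vi
    name: Pregnant women tested for syphilis
    programme_area: antenatal care
  - code: vii
    name: Pregnant women tested for HIV
    programme_area: antenatal care
  - code: viii
    name: Pregnant women receiving iron and folic acid
    programme_area: antenatal care
  - code: ix
    name: Children with first dose of pentavalent vaccine
    programme_area: immunization
  - code: x
    name: Children with third dose of pentavalent vaccine
    programme_area: immunization
  - code: xi
    name: Children with first dose of rotavirus vaccine
    programme_area: immunization
  - code: xii
    name: Children with second dose of rotavirus vaccine
    programme_area: immunization
  - code: xiii
    name: People still on ART 12 months after initiation
    programme_area: HIV
  - code: xiv
    name: People initiated on ART
    programme_area: HIV
  - code: xv
    name: ART patients with an undetectable viral load (<50 copies/mL)
    programme_area: HIV
  - code: xvi
    name: ART patients with a viral load test done at 12 months
    programme_area: HIV
  - code: xvii
    name: Tuberculosis patients cured
    programme_area: tuberculosis
  - code: xviii
    name: Tuberculosis patients on treatment
    programme_area: tuberculosis
  - code: xix
    name: Hypertensive patients with controlled blood pressure at 6 months
    programme_area: hypertension
  - code: xx
    name: Hypertensive patients enrolled in care 6 months prior
    programme_area: hypertension
  - code: xxi
    name: Diabetic patients with controlled blood sugar at 6 months
    programme_area: diabetes
  - code: xxii
    name: Diabetic patients enrolled in care 6 months prior
    programme_area: diabetes
  - code: xxiii
    name: Patient encounters with one or more antibiotics
    programme_area: antibiotics
  - code: xxiv
    name: Total patient encounters at facilities
    programme_area: antibiotics
  - code: xxv
    name: Total outpatient visits
    programme_area: outpatient
  - code: xxvi
    name: New and repeat acceptors of oral contraceptives
    programme_area: reproductive health
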