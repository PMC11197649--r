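# Which data elements each facility tier collects. "all" = every catalogue
# element. Health posts (rural community tier) report antenatal visit
# counts, iron/folic acid, childhood immunisation, oral contraceptives and
# outpatient volume, but not delivery care, antenatal lab testing, ART,
# tuberculosis, NCD or antibiotic-stewardship elements.
applicability:
  health_post: [iii, iv, v, viii, ix, x, xi, xii, xxv, xxvi]
  health_centre: all
  public_hospital: all
  private_clinic: all
  private_hospital: all
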