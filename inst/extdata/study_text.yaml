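name: study_text
description: >
  Screening-cascade and diagnostic counts of the motivating
  active-case-ascertainment study of elementary-school students, as
  reported in the study's narrative text and recruitment flow diagram.
  This is the canonical count set: it reproduces the study's printed
  FAS and pFAS prevalence estimates exactly.
provenance:
  cascade: study narrative (recruitment and screening results) and flow diagram
  diagnosis: study narrative (suspected and deferred cases; control-arm findings)
  tables: printed case/control comparison table of growth and dysmorphology
cascade:
  n_invited: 8209
  n_responded: 3854
  n_consented: 2693
  n_phase1_assessed: 2555
  n_phase2_selected: 793
  n_phase2_assessed: 762
  n_deficit2plus: 323
  n_interviewed: 132
  n_cbcl: 136
allow_inconsistent: false
diagnosis:
  n_fas: 3
  n_pfas: 2
  n_arnd: 16
  n_deferred: 5
  n_tdcc_assessed: 84
  n_tdcc_cases:
    FAS: 0
    pFAS: 0
    ARND: 1
reported:
  stage_percent:
    responded: 46.9
    consented: 69.9
    phase2_selected: 31.0
    deficit2plus: 42.4
    interviewed: 40.9
  main:
    FAS: 1.2
    pFAS: 2.0
    ARND: 15.0
    FASD_total: 18.1
  sensitivity:
    FAS: 1.2
    pFAS: 2.0
    ARND: 26.1
    FASD_total: 29.3
  main_ci:
    FAS: [0.0, 2.8]
    pFAS: [0.0, 5.1]
    ARND: [8.1, 22.7]
    FASD_total: [10.8, 26.3]
  sensitivity_ci:
    FAS: [0.0, 2.8]
    pFAS: [0.0, 5.1]
    ARND: [9.6, 52.8]
    FASD_total: [12.4, 56.2]
tables:
  height_le_10th_pct:
    a: 5
    b: 16
    c: 2
    d: 81
    reported_chi2: 12.226
  weight_le_10th_pct:
    a: 4
    b: 17
    c: 7
    d: 76
    reported_chi2: 1.996
  ofc_le_10th_pct:
    a: 5
    b: 16
    c: 0
    d: 83
    reported_chi2: 20.760
  right_pfl_2sd_below:
    a: 10
    b: 11
    c: 9
    d: 74
    reported_chi2: 15.180
  left_pfl_2sd_below:
    a: 9
    b: 12
    c: 11
    d: 72
    reported_chi2: 9.456
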