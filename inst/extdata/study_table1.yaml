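name: study_table1
description: >
  Alternative count set in which Phase II eligibility and completion
  follow the study's printed comparison table (817 eligible for Phase
  II; footnote reporting 786 completing the neurodevelopmental
  assessment) instead of the narrative text (793 selected / 762
  assessed).  The two sources disagree internally; this variant does
  NOT reproduce the printed FAS/pFAS prevalence estimates and is
  provided for sensitivity checking only.  Whether the 817 figure
  includes control children or re-screened students is not stated.
provenance:
  cascade: printed comparison-table column headers and footnotes; other
    counts from the study narrative
  diagnosis: study narrative (suspected and deferred cases; control-arm findings)
cascade:
  n_invited: 8209
  n_responded: 3854
  n_consented: 2693
  n_phase1_assessed: 2555
  n_phase2_selected: 817
  n_phase2_assessed: 786
  n_deficit2plus: 323
  n_interviewed: 132
  n_cbcl: 136
allow_inconsistent: true
inconsistent_with_text: true
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
reported: {}
tables: {}
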