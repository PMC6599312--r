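# shared fixtures and independent oracles

study_cascade <- function(...) {
  screening_cascade(n_invited = 8209, n_responded = 3854, n_consented = 2693,
                    n_phase1_assessed = 2555, n_phase2_selected = 793,
                    n_phase2_assessed = 762, n_deficit2plus = 323,
                    n_interviewed = 132, n_cbcl = 136, ...)
}

study_dx <- function(...) {
  diagnosis_counts(n_fas = 3, n_pfas = 2, n_arnd = 16, n_deferred = 5,
                   n_tdcc_assessed = 84, n_tdcc_cases = c(ARND = 1), ...)
}

# brute-force oracle: recompute plug-in estimates directly from raw
# child records, bypassing the cascade/diagnosis containers entirely
oracle_from_records <- function(children) {
  n_p1 <- sum(children$assessed_p1)
  n_sel <- sum(children$selected)
  n_p2 <- sum(children$assessed_p2)
  n_def <- sum(children$deficit2plus)
  n_int <- sum(children$interviewed)
  fas <- sum(children$assessed_p2 & children$true_status == "FAS")
  pfas <- sum(children$interviewed & children$true_status == "pFAS")
  arnd <- sum(children$interviewed & children$true_status == "ARND")
  out <- c(
    FAS = 1000 * (n_sel / n_p1) * (fas / n_p2),
    pFAS = 1000 * (n_sel / n_p1) * (n_def / n_p2) * (pfas / n_int),
    ARND = 1000 * (n_sel / n_p1) * (n_def / n_p2) * (arnd / n_int))
  c(out, FASD_total = sum(out))
}
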