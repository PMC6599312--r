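test_that("config validation names the offending field", {
  expect_error(cohort_config(participation = list(respond = 1.5, consent = 1,
                                                  assess_phase1 = 1,
                                                  assess_phase2 = 1,
                                                  interview = 1, cbcl = 1)),
               "respond")
  expect_error(cohort_config(true_prev = c(FAS = 600, pFAS = 300, ARND = 200)),
               "true_prev")
  expect_error(cohort_config(phase1_sensitivity = c(FAS = 2, pFAS = 1, ARND = 1)),
               "phase1_sensitivity")
})

test_that("derived cascade passes validation and seeded runs reproduce", {
  cfg <- cohort_config(n_children = 5000, seed = 101)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1$children, coh2$children)
  expect_s3_class(coh1$cascade, "screening_cascade")  # built without override
  expect_false(attr(coh1$cascade, "allow_inconsistent"))
  # cascade counts equal record column sums
  expect_equal(unname(coh1$cascade["phase2_selected"]),
               sum(coh1$children$selected))
  expect_equal(unname(coh1$cascade["interviewed"]),
               sum(coh1$children$interviewed))
})

test_that("zero prevalence yields zero diagnostic counts", {
  cfg <- cohort_config(n_children = 3000,
                       true_prev = c(FAS = 0, pFAS = 0, ARND = 0), seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(coh$dx$n_fas + coh$dx$n_pfas + coh$dx$n_arnd + coh$dx$n_deferred, 0)
})

test_that("perfect screening and participation observes every true case", {
  cfg <- cohort_config(
    n_children = 20000, true_prev = c(FAS = 5, pFAS = 5, ARND = 20),
    phase1_positive_rate_controls = 0,
    participation = list(respond = 1, consent = 1, assess_phase1 = 1,
                         assess_phase2 = 1, interview = 1, cbcl = 1),
    seed = 7)
  coh <- generate_cohort(cfg)
  st <- coh$children$true_status
  expect_equal(coh$dx$n_fas, sum(st == "FAS"))
  expect_equal(coh$dx$n_pfas, sum(st == "pFAS"))
  expect_equal(coh$dx$n_arnd, sum(st == "ARND"))
  # and the plug-in estimator recovers the empirical prevalence exactly
  est <- estimate_total(coh$cascade, coh$dx, "main")$per_1000
  expect_equal(est, 1000 * mean(st != "none"), tolerance = 1e-12)
})

test_that("expected stage counts follow the binomial chain", {
  cfg <- cohort_config(n_children = 100000, seed = 23)
  coh <- generate_cohort(cfg)
  part <- cfg$participation
  p_case <- sum(cfg$true_prev) / 1000
  p_pos <- p_case + (1 - p_case) * cfg$phase1_positive_rate_controls
  p_sel <- part$respond * part$consent * part$assess_phase1 * p_pos
  expected <- cfg$n_children * p_sel
  sd_bin <- sqrt(cfg$n_children * p_sel * (1 - p_sel))
  expect_lt(abs(unname(coh$cascade["phase2_selected"]) - expected), 4 * sd_bin)
})

test_that("full-participation large cohort recovers an 18-per-1000 prevalence", {
  cfg <- cohort_config(
    n_children = 100000, true_prev = c(FAS = 6, pFAS = 4, ARND = 8),
    phase1_positive_rate_controls = 0,
    participation = list(respond = 1, consent = 1, assess_phase1 = 1,
                         assess_phase2 = 1, interview = 1, cbcl = 1),
    seed = 31)
  coh <- generate_cohort(cfg)
  est <- estimate_total(coh$cascade, coh$dx, "main")$per_1000
  # oracle: empirical proportion of true cases (law of large numbers)
  expect_lt(abs(est - 18), 1.5)
  expect_equal(est, 1000 * mean(coh$children$true_status != "none"),
               tolerance = 1e-12)
})

test_that("plug-in estimates equal brute-force enumeration on small cohorts", {
  for (seed in c(2, 3, 4, 8)) {
    cfg <- cohort_config(n_children = 500,
                         true_prev = c(FAS = 20, pFAS = 20, ARND = 60),
                         participation = list(respond = 0.9, consent = 0.9,
                                              assess_phase1 = 0.95,
                                              assess_phase2 = 0.95,
                                              interview = 0.8, cbcl = 0.5),
                         seed = seed)
    coh <- generate_cohort(cfg)
    if (unname(coh$cascade["interviewed"]) == 0) next
    oracle <- oracle_from_records(coh$children)
    for (cat in fasd_categories())
      expect_equal(estimate_prevalence(coh$cascade, coh$dx, cat)$per_1000,
                   unname(oracle[cat]), tolerance = 1e-12)
  }
})

test_that("recovery experiment is unbiased under MAR interview dropout", {
  cfg <- cohort_config(n_children = 40000,
                       true_prev = c(FAS = 4, pFAS = 4, ARND = 16),
                       participation = list(respond = 0.9, consent = 0.9,
                                            assess_phase1 = 0.95,
                                            assess_phase2 = 0.96,
                                            interview = 0.4, cbcl = 0.4),
                       seed = 77)
  res <- recovery_experiment(cfg, n_sim = 60)
  expect_true(all(abs(res$relative_bias) < 0.08))
  expect_true(all(is.na(res$ci_coverage)))
})

test_that("status-correlated interview dropout biases pFAS/ARND downward", {
  cfg <- cohort_config(n_children = 40000,
                       true_prev = c(FAS = 4, pFAS = 6, ARND = 16),
                       interview_case_multiplier = 0.5, seed = 13)
  res <- recovery_experiment(cfg, n_sim = 40, categories = c("pFAS", "ARND"))
  expect_true(all(res$relative_bias < -0.2))
})

test_that("one-replicate experiment aggregates without error", {
  cfg <- cohort_config(n_children = 20000, seed = 3)
  res <- recovery_experiment(cfg, n_sim = 1,
                             mc = mc_settings(n_reps = 500, seed = 3))
  expect_equal(nrow(res), 4)
  expect_true(all(res$ci_coverage %in% c(0, 1)))
})

test_that("higher interview participation does not inflate estimator spread", {
  spread <- function(p_int) {
    cfg <- cohort_config(n_children = 30000,
                         true_prev = c(FAS = 4, pFAS = 4, ARND = 16),
                         participation = list(respond = 0.9, consent = 0.9,
                                              assess_phase1 = 0.95,
                                              assess_phase2 = 0.96,
                                              interview = p_int, cbcl = 0.4),
                         seed = 55)  # common random numbers across settings
    ests <- numeric(50)
    for (i in seq_along(ests)) {
      cfg$seed <- 55 + i
      coh <- generate_cohort(cfg)
      ests[i] <- estimate_prevalence(coh$cascade, coh$dx, "ARND")$per_1000
    }
    stats::sd(ests)
  }
  expect_lte(spread(0.8), spread(0.3))
})

test_that("cohorts round-trip through CSV", {
  coh <- generate_cohort(cohort_config(n_children = 200, seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(nrow(back), 200)
  expect_equal(back$true_status, coh$children$true_status)
  expect_equal(back$interviewed, coh$children$interviewed)
})
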