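test_that("FAS and pFAS plug-in estimates reproduce the printed values", {
  casc <- study_cascade()
  dx <- study_dx()
  fas <- estimate_fas(casc, dx)
  expect_equal(fas$per_1000, 1000 * (793 / 2555) * (3 / 762), tolerance = 1e-15)
  expect_equal(render_per_1000(fas$per_1000), 1.2)
  pfas <- estimate_interview_category(casc, dx, "pFAS")
  expect_equal(pfas$per_1000, 1000 * (793 / 2555) * (323 / 762) * (2 / 132),
               tolerance = 1e-15)
  expect_equal(render_per_1000(pfas$per_1000), 2.0)
})

test_that("ARND and total carry the documented plug-in values", {
  casc <- study_cascade()
  dx <- study_dx()
  arnd <- estimate_interview_category(casc, dx, "ARND")
  expect_equal(render_per_1000(arnd$per_1000), 15.9)
  tot <- estimate_total(casc, dx, "main")
  expect_equal(render_per_1000(tot$per_1000), 19.2)
  expect_equal(tot$per_1000,
               estimate_fas(casc, dx)$per_1000 + arnd$per_1000 +
                 estimate_interview_category(casc, dx, "pFAS")$per_1000,
               tolerance = 1e-9)
})

test_that("degenerate and hand-computed estimator cases", {
  casc <- screening_cascade(100, 100, 100, 100, 100, 100, 100, 100, 100)
  dx5 <- diagnosis_counts(5, 0, 0)
  expect_equal(estimate_fas(casc, dx5)$per_1000, 50)  # 1000 * 1 * 5/100
  expect_equal(estimate_fas(casc, diagnosis_counts(0, 0, 0))$per_1000, 0)
  # saturation: every interviewed child a case, all proportions 1
  dx_sat <- diagnosis_counts(0, 0, 100)
  expect_equal(estimate_interview_category(casc, dx_sat, "ARND")$per_1000, 1000)
  # zero-denominator errors name the stage
  empty <- screening_cascade(10, 5, 3, 0, 0, 0, 0, 0, 0)
  expect_error(estimate_fas(empty, dx5), "phase1_assessed")
  no_int <- screening_cascade(100, 90, 80, 70, 30, 25, 10, 0, 0)
  expect_error(estimate_interview_category(no_int, dx5, "pFAS"), "interviewed")
})

test_that("sensitivity extrapolation adds the control-arm rate over negatives", {
  casc <- study_cascade()
  dx <- study_dx()
  arnd_main <- estimate_interview_category(casc, dx, "ARND")$per_1000
  sens <- estimate_sensitivity(casc, dx, "ARND", "pre_interview_negatives")
  expect_equal(sens$per_1000,
               arnd_main + 1000 * (1 / 84) * ((2555 - 323) / 2555),
               tolerance = 1e-12)
  expect_equal(render_per_1000(sens$per_1000), 26.3)
  # categories with zero control-arm cases are unchanged, as printed
  for (cat in c("FAS", "pFAS")) {
    s <- estimate_sensitivity(casc, dx, cat)
    m <- estimate_prevalence(casc, dx, cat, "main")
    expect_equal(s$per_1000, m$per_1000)
  }
  expect_equal(render_per_1000(estimate_sensitivity(casc, dx, "FAS")$per_1000), 1.2)
  expect_equal(render_per_1000(estimate_sensitivity(casc, dx, "pFAS")$per_1000), 2.0)
  # all three negative bases computable and ordered by base size
  v <- sapply(negative_bases(), function(b)
    estimate_sensitivity(casc, dx, "ARND", b)$per_1000)
  expect_true(v["phase1_negatives"] < v["pre_interview_negatives"])
  expect_true(v["pre_interview_negatives"] < v["pre_conference_negatives"])
  expect_error(estimate_sensitivity(casc, dx, "ARND", "bogus"))
})

test_that("sensitivity estimate is never below the main estimate", {
  casc <- study_cascade()
  set.seed(42)
  for (i in 1:25) {
    dx <- diagnosis_counts(sample(0:5, 1), sample(0:5, 1), sample(0:20, 1),
                           n_tdcc_assessed = 84,
                           n_tdcc_cases = c(FAS = sample(0:2, 1),
                                            pFAS = sample(0:2, 1),
                                            ARND = sample(0:3, 1)))
    base <- sample(negative_bases(), 1)
    for (cat in fasd_categories()) {
      main <- estimate_prevalence(casc, dx, cat, "main")$per_1000
      sens <- estimate_prevalence(casc, dx, cat, "sensitivity", base)$per_1000
      expect_gte(sens, main)
    }
  }
})

test_that("estimates are scale-invariant and ignore the CBCL count", {
  dx <- study_dx()
  base <- study_cascade()
  for (k in c(2, 7)) {
    scaled <- screening_cascade(8209 * k, 3854 * k, 2693 * k, 2555 * k,
                                793 * k, 762 * k, 323 * k, 132 * k, 136 * k)
    dx_k <- diagnosis_counts(3 * k, 2 * k, 16 * k, 5 * k,
                             n_tdcc_assessed = 84 * k,
                             n_tdcc_cases = c(ARND = 1 * k))
    for (cat in fasd_categories()) {
      expect_equal(estimate_prevalence(scaled, dx_k, cat, "main")$per_1000,
                   estimate_prevalence(base, dx, cat, "main")$per_1000,
                   tolerance = 1e-12)
      expect_equal(
        estimate_prevalence(scaled, dx_k, cat, "sensitivity")$per_1000,
        estimate_prevalence(base, dx, cat, "sensitivity")$per_1000,
        tolerance = 1e-12)
    }
  }
  other_cbcl <- screening_cascade(8209, 3854, 2693, 2555, 793, 762, 323, 132, 0)
  for (cat in fasd_categories())
    expect_equal(estimate_prevalence(other_cbcl, dx, cat, "main")$per_1000,
                 estimate_prevalence(base, dx, cat, "main")$per_1000)
})

test_that("total is linear in case counts and equals the category sum", {
  casc <- study_cascade()
  dx <- study_dx()
  dbl <- diagnosis_counts(6, 4, 32, 10, n_tdcc_assessed = 84,
                          n_tdcc_cases = c(ARND = 2))
  expect_equal(estimate_total(casc, dbl, "main")$per_1000,
               2 * estimate_total(casc, dx, "main")$per_1000,
               tolerance = 1e-12)
  expect_equal(estimate_total(casc, diagnosis_counts(0, 0, 0))$per_1000, 0)
  for (mode in c("main", "sensitivity")) {
    tot <- estimate_prevalence(casc, dx, "FASD_total", mode)$per_1000
    parts <- sum(sapply(c("FAS", "pFAS", "ARND"), function(cat)
      estimate_prevalence(casc, dx, cat, mode)$per_1000))
    expect_equal(tot, parts, tolerance = 1e-9)
  }
})
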