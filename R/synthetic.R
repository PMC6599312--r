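#' Configuration for a synthetic screening cohort
#'
#' Describes a child cohort with known true diagnostic status and the
#' multi-phase screening/attrition structure of an active-case-
#' ascertainment study: a Phase I screen (growth, sentinel facial
#' features, behavioural/learning history collapsed to one binary
#' "meets any criterion" indicator), a Phase II neurodevelopmental
#' assessment with a two-plus-domain deficit threshold, a maternal
#' interview, and per-stage Bernoulli participation.
#'
#' Defaults emulate the motivating study's observed cascade: 46.9%
#' parental response, 69.9% consent, 94.9% Phase I completion, 96.1%
#' Phase II completion, 40.9% interview completion; control-child
#' positive rates are calibrated so that roughly 31% of assessed
#' children are selected for Phase II and 42% of Phase II completers
#' cross the deficit threshold.  Screening sensitivities for true cases
#' default to 1, which is the identifying assumption of the plug-in
#' estimator itself; lower them to study the resulting downward bias.
#'
#' @param n_children cohort size (consent forms distributed).
#' @param true_prev named per-1000 true prevalences for
#'   `FAS`, `pFAS`, `ARND`; must sum to < 1000.
#' @param phase1_sensitivity named probabilities that a true case of
#'   each category meets at least one Phase I criterion.
#' @param phase1_positive_rate_controls probability a non-case meets at
#'   least one Phase I criterion.
#' @param deficit2plus_sensitivity named probabilities that a true case
#'   shows deficits in two or more neurodevelopmental domains.
#' @param deficit2plus_rate_controls analogous rate for non-cases.
#' @param participation list of per-stage completion probabilities:
#'   `respond`, `consent`, `assess_phase1`, `assess_phase2`,
#'   `interview`, `cbcl`.
#' @param interview_case_multiplier multiplies the interview completion
#'   probability for true cases (1 = missing at random; < 1 makes cases
#'   less likely to be interviewed, breaking the estimator's
#'   assumption).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_children = 10000,
                          true_prev = c(FAS = 1.2, pFAS = 2.0, ARND = 16.0),
                          phase1_sensitivity = c(FAS = 1, pFAS = 1, ARND = 1),
                          phase1_positive_rate_controls = 0.297,
                          deficit2plus_sensitivity = c(FAS = 1, pFAS = 1, ARND = 1),
                          deficit2plus_rate_controls = 0.386,
                          participation = list(respond = 0.469, consent = 0.699,
                                               assess_phase1 = 0.949,
                                               assess_phase2 = 0.961,
                                               interview = 0.409, cbcl = 0.421),
                          interview_case_multiplier = 1,
                          seed = NULL) {
  cats <- c("FAS", "pFAS", "ARND")
  n_children <- check_count(n_children, "n_children")
  if (n_children < 1) stop("n_children must be >= 1", call. = FALSE)
  if (!all(cats %in% names(true_prev)))
    stop("true_prev must name FAS, pFAS and ARND", call. = FALSE)
  true_prev <- true_prev[cats]
  if (any(true_prev < 0) || sum(true_prev) >= 1000)
    stop("true_prev entries must be >= 0 and sum to < 1000 per 1000",
         call. = FALSE)
  norm_sens <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 3), cats)
    if (!all(cats %in% names(x)))
      stop(sprintf("'%s' must name FAS, pFAS and ARND", name), call. = FALSE)
    check_prob(x[cats], name)
  }
  phase1_sensitivity <- norm_sens(phase1_sensitivity, "phase1_sensitivity")
  deficit2plus_sensitivity <- norm_sens(deficit2plus_sensitivity,
                                        "deficit2plus_sensitivity")
  check_prob(phase1_positive_rate_controls, "phase1_positive_rate_controls")
  check_prob(deficit2plus_rate_controls, "deficit2plus_rate_controls")
  needed <- c("respond", "consent", "assess_phase1", "assess_phase2",
              "interview", "cbcl")
  if (!all(needed %in% names(participation)))
    stop("participation must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  for (s in needed) check_prob(participation[[s]], paste0("participation$", s))
  check_prob(interview_case_multiplier * participation$interview,
             "interview probability for cases (after multiplier)")

  structure(list(n_children = n_children, true_prev = true_prev,
                 phase1_sensitivity = phase1_sensitivity,
                 phase1_positive_rate_controls = phase1_positive_rate_controls,
                 deficit2plus_sensitivity = deficit2plus_sensitivity,
                 deficit2plus_rate_controls = deficit2plus_rate_controls,
                 participation = participation[needed],
                 interview_case_multiplier = interview_case_multiplier,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic screening cohort
#'
#' Draws child-level records independently: true status multinomial
#' from `true_prev`, then stage-by-stage Bernoulli participation and
#' screening outcomes conditional on the preceding stage.  A child's
#' diagnosis is observable only if the study design would have
#' observed it: FAS on completing the Phase II assessment; pFAS/ARND
#' only with a completed maternal interview.  ARND-status children who
#' miss the two-domain deficit threshold are counted as deferred and
#' treated as screen-negative.
#'
#' @param config a [cohort_config].
#' @return an object of class `synthetic_cohort`: a list with
#'   `children` (one row per child), `cascade` (the derived
#'   [screening_cascade], column sums of the records) and `dx` (the
#'   derived [diagnosis_counts]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_children
  part <- config$participation
  cats <- c("FAS", "pFAS", "ARND")

  p <- config$true_prev / 1000
  status <- sample(c(cats, "none"), n, replace = TRUE,
                   prob = c(p, 1 - sum(p)))
  is_case <- status != "none"

  bern <- function(prob) stats::rbinom(n, 1L, prob) == 1L

  responded <- bern(part$respond)
  consented <- responded & bern(part$consent)
  assessed_p1 <- consented & bern(part$assess_phase1)

  p1pos_prob <- ifelse(is_case, config$phase1_sensitivity[status],
                       config$phase1_positive_rate_controls)
  phase1_positive <- bern(p1pos_prob)
  selected <- assessed_p1 & phase1_positive
  assessed_p2 <- selected & bern(part$assess_phase2)

  def_prob <- ifelse(is_case, config$deficit2plus_sensitivity[status],
                     config$deficit2plus_rate_controls)
  deficit_latent <- bern(def_prob)
  deficit2plus <- assessed_p2 & deficit_latent

  int_prob <- ifelse(is_case,
                     part$interview * config$interview_case_multiplier,
                     part$interview)
  interviewed <- deficit2plus & bern(int_prob)
  cbcl <- deficit2plus & bern(part$cbcl)

  # a diagnosis is observable only at the stage its category requires:
  # FAS at the Phase II assessment, pFAS/ARND at the maternal interview;
  # non-cases are confirmed "none" only once interviewed
  observed <- rep("unobserved", n)
  observed[assessed_p2 & status == "FAS"] <- "FAS"
  observed[interviewed & status == "pFAS"] <- "pFAS"
  observed[interviewed & status == "ARND"] <- "ARND"
  observed[interviewed & status == "none"] <- "none"

  children <- data.frame(
    true_status = status, phase1_positive = phase1_positive,
    deficit2plus = deficit2plus, responded = responded,
    consented = consented, assessed_p1 = assessed_p1,
    selected = selected, assessed_p2 = assessed_p2,
    interviewed = interviewed, cbcl = cbcl,
    observed_diagnosis = observed, stringsAsFactors = FALSE)

  cascade <- screening_cascade(
    n_invited = n, n_responded = sum(responded),
    n_consented = sum(consented), n_phase1_assessed = sum(assessed_p1),
    n_phase2_selected = sum(selected), n_phase2_assessed = sum(assessed_p2),
    n_deficit2plus = sum(deficit2plus), n_interviewed = sum(interviewed),
    n_cbcl = sum(cbcl))

  dx <- diagnosis_counts(
    n_fas = sum(assessed_p2 & status == "FAS"),
    n_pfas = sum(interviewed & status == "pFAS"),
    n_arnd = sum(interviewed & status == "ARND"),
    n_deferred = sum(assessed_p2 & status == "ARND" & !deficit_latent))

  structure(list(children = children, cascade = cascade, dx = dx,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic screening cohort: %d children\n",
              nrow(x$children)))
  cat(sprintf("  true cases: FAS %d, pFAS %d, ARND %d\n",
              sum(x$children$true_status == "FAS"),
              sum(x$children$true_status == "pFAS"),
              sum(x$children$true_status == "ARND")))
  print(x$cascade)
  invisible(x)
}

#' Write / read a synthetic cohort's child records as CSV
#'
#' @param cohort a `synthetic_cohort`.
#' @param path CSV file path.
#' @return the path invisibly / a `data.frame` of child records.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  utils::write.csv(cohort$children, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates cohorts, runs the plug-in estimators (and,
#' optionally, Monte Carlo CIs) on the derived counts, and summarises
#' per-category bias and CI coverage of the true prevalence.
#'
#' @param config a [cohort_config]; its `seed` (default 1 when `NULL`)
#'   seeds replicate `i` with `seed + i`.
#' @param n_sim number of simulated cohorts.
#' @param mc an [mc_settings] for per-replicate CIs, or `NULL` to skip
#'   coverage.
#' @param categories categories to track.
#' @return a `data.frame` with one row per category: `true_per_1000`,
#'   `mean_estimate`, `relative_bias`, `ci_coverage` (`NA` without
#'   `mc`), `n_sim`.
#' @export
recovery_experiment <- function(config, n_sim, mc = NULL,
                                categories = fasd_categories()) {
  stopifnot(inherits(config, "cohort_config"), n_sim >= 1)
  if (!is.null(mc)) stopifnot(inherits(mc, "mc_settings"))
  base_seed <- if (is.null(config$seed)) 1L else config$seed
  truth <- c(config$true_prev, FASD_total = sum(config$true_prev))[categories]

  est <- matrix(NA_real_, n_sim, length(categories),
                dimnames = list(NULL, categories))
  cover <- matrix(NA, n_sim, length(categories),
                  dimnames = list(NULL, categories))
  for (i in seq_len(n_sim)) {
    cfg_i <- config
    cfg_i$seed <- base_seed + i
    coh <- generate_cohort(cfg_i)
    for (cat in categories) {
      e <- estimate_prevalence(coh$cascade, coh$dx, cat)
      est[i, cat] <- e$per_1000
      if (!is.null(mc)) {
        mc_i <- mc
        mc_i$seed <- base_seed + i  # replicate-specific CI seed
        ci <- percentile_ci(
          simulate_prevalence_reps(coh$cascade, coh$dx, cat, "main", mc_i),
          mc$ci_level)
        cover[i, cat] <- ci["low"] <= truth[[cat]] && truth[[cat]] <= ci["high"]
      }
    }
  }
  data.frame(
    category = categories,
    true_per_1000 = unname(truth),
    mean_estimate = colMeans(est),
    relative_bias = (colMeans(est) - unname(truth)) / unname(truth),
    ci_coverage = if (is.null(mc)) NA_real_ else colMeans(cover),
    n_sim = n_sim, row.names = NULL, stringsAsFactors = FALSE)
}
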