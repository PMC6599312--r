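#' Screen-negative base populations for the sensitivity analysis
#'
#' The sensitivity analysis extrapolates the case rate observed among
#' assessed control children to the children who never reached a
#' diagnosis.  "Screen-negative" can be drawn at three points of the
#' cascade; the published analysis does not state which, so all three
#' are available:
#' \describe{
#'   \item{phase1_negatives}{`n_phase1_assessed - n_phase2_selected`:
#'     children never selected into Phase II.}
#'   \item{pre_interview_negatives}{`n_phase1_assessed - n_deficit2plus`
#'     (default): children who never met the two-domain deficit
#'     threshold.}
#'   \item{pre_conference_negatives}{`n_phase1_assessed - n_interviewed`:
#'     children whose mothers were never interviewed.}
#' }
#'
#' @return character vector of valid base names.
#' @export
negative_bases <- function() {
  c("pre_interview_negatives", "phase1_negatives", "pre_conference_negatives")
}

# internal: count of screen-negative children under a named base
negative_base_count <- function(cascade, negative_base) {
  if (!negative_base %in% negative_bases())
    stop(sprintf("unknown negative_base '%s'; valid options: %s",
                 negative_base, paste(negative_bases(), collapse = ", ")),
         call. = FALSE)
  n1 <- stage_count(cascade, "phase1_assessed")
  switch(negative_base,
    phase1_negatives = n1 - stage_count(cascade, "phase2_selected"),
    pre_interview_negatives = n1 - stage_count(cascade, "deficit2plus"),
    pre_conference_negatives = n1 - stage_count(cascade, "interviewed"))
}

# internal: constructor for the estimate container
new_prevalence_estimate <- function(category, mode, per_1000, inputs,
                                    ci_low = NA_real_, ci_high = NA_real_) {
  structure(list(category = category, mode = mode, per_1000 = per_1000,
                 ci_low = ci_low, ci_high = ci_high,
                 inputs_digest = inputs),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  ci <- if (!is.na(x$ci_low))
    sprintf(" (95%% CI %.1f-%.1f)", render_per_1000(x$ci_low),
            render_per_1000(x$ci_high)) else ""
  cat(sprintf("%s prevalence (%s analysis): %.1f per 1000%s  [unrounded %.6g]\n",
              x$category, x$mode, render_per_1000(x$per_1000), ci, x$per_1000))
  invisible(x)
}

# internal: require a positive denominator, error names the stage
require_positive <- function(n, stage) {
  if (n <= 0)
    stop(sprintf("stage '%s' has zero count; estimate undefined", stage),
         call. = FALSE)
  n
}

#' Selection-rate-adjusted FAS prevalence
#'
#' Plug-in estimate per 1000 children:
#' `1000 * (n_phase2_selected / n_phase1_assessed) * (n_fas / n_phase2_assessed)`.
#' FAS is the one category diagnosable without the maternal interview
#' (its growth and sentinel facial criteria suffice), so its case rate
#' is taken over all children completing the neurodevelopmental
#' assessment rather than over interviewed children.
#'
#' @param cascade a [screening_cascade].
#' @param dx a [diagnosis_counts].
#' @return a `prevalence_estimate`.
#' @export
estimate_fas <- function(cascade, dx) {
  n1 <- require_positive(stage_count(cascade, "phase1_assessed"), "phase1_assessed")
  n2a <- require_positive(stage_count(cascade, "phase2_assessed"), "phase2_assessed")
  sel <- stage_count(cascade, "phase2_selected")
  per_1000 <- 1000 * (sel / n1) * (dx$n_fas / n2a)
  new_prevalence_estimate("FAS", "main", per_1000, inputs = list(
    formula = "1000 * (phase2_selected/phase1_assessed) * (n_fas/phase2_assessed)",
    counts = c(phase2_selected = sel, phase1_assessed = n1,
               n_fas = dx$n_fas, phase2_assessed = n2a)))
}

#' Selection-rate-adjusted prevalence for interview-dependent categories
#'
#' pFAS and ARND require a confirmed prenatal-alcohol-exposure history,
#' obtained only for interviewed mothers, so their case rate is taken
#' over interviewed children and back-projected through two selection
#' proportions:
#' `1000 * (n_phase2_selected / n_phase1_assessed) *
#'  (n_deficit2plus / n_phase2_assessed) * (n_category / n_interviewed)`.
#' The estimator assumes interview non-completion is independent of
#' diagnostic status (missing at random).
#'
#' @param cascade a [screening_cascade].
#' @param dx a [diagnosis_counts].
#' @param category `"pFAS"` or `"ARND"`.
#' @return a `prevalence_estimate`.
#' @export
estimate_interview_category <- function(cascade, dx,
                                        category = c("pFAS", "ARND")) {
  category <- match.arg(category)
  n1 <- require_positive(stage_count(cascade, "phase1_assessed"), "phase1_assessed")
  n2a <- require_positive(stage_count(cascade, "phase2_assessed"), "phase2_assessed")
  n_int <- require_positive(stage_count(cascade, "interviewed"), "interviewed")
  sel <- stage_count(cascade, "phase2_selected")
  def <- stage_count(cascade, "deficit2plus")
  k <- dx_count(dx, category)
  per_1000 <- 1000 * (sel / n1) * (def / n2a) * (k / n_int)
  new_prevalence_estimate(category, "main", per_1000, inputs = list(
    formula = paste0("1000 * (phase2_selected/phase1_assessed) * ",
                     "(deficit2plus/phase2_assessed) * (n_", tolower(category),
                     "/interviewed)"),
    counts = c(phase2_selected = sel, phase1_assessed = n1,
               deficit2plus = def, phase2_assessed = n2a,
               n_cases = k, interviewed = n_int)))
}

#' Screen-negative extrapolation (sensitivity analysis)
#'
#' Adds to the main estimate the case rate observed among assessed
#' control children, extrapolated over the screen-negative fraction of
#' the Phase I population:
#' `main + 1000 * (n_tdcc_cases[category] / n_tdcc_assessed) *
#'  (N_negative / n_phase1_assessed)`
#' where `N_negative` is defined by `negative_base` (see
#' [negative_bases()]).  With zero control-arm cases the sensitivity
#' estimate equals the main estimate.
#'
#' @param cascade a [screening_cascade].
#' @param dx a [diagnosis_counts] with `n_tdcc_assessed > 0`.
#' @param category `"FAS"`, `"pFAS"` or `"ARND"`.
#' @param negative_base screen-negative population definition.
#' @return a `prevalence_estimate` with `mode = "sensitivity"`.
#' @export
estimate_sensitivity <- function(cascade, dx, category,
                                 negative_base = negative_bases()) {
  negative_base <- match.arg(negative_base)
  main <- if (category == "FAS") estimate_fas(cascade, dx)
          else estimate_interview_category(cascade, dx, category)
  n_tdcc <- require_positive(dx$n_tdcc_assessed, "tdcc_assessed")
  n1 <- stage_count(cascade, "phase1_assessed")
  n_neg <- negative_base_count(cascade, negative_base)
  extra <- 1000 * (dx$n_tdcc_cases[[category]] / n_tdcc) * (n_neg / n1)
  new_prevalence_estimate(category, "sensitivity", main$per_1000 + extra,
    inputs = c(main$inputs_digest, list(
      negative_base = negative_base,
      extrapolation = c(n_tdcc_cases = dx$n_tdcc_cases[[category]],
                        n_tdcc_assessed = n_tdcc, n_negative = n_neg,
                        phase1_assessed = n1))))
}

#' Total FASD prevalence
#'
#' Sum of the FAS, pFAS and ARND estimates computed under the same mode
#' and counts.
#'
#' @inheritParams estimate_sensitivity
#' @param mode `"main"` or `"sensitivity"`.
#' @return a `prevalence_estimate` for `FASD_total`.
#' @export
estimate_total <- function(cascade, dx, mode = c("main", "sensitivity"),
                           negative_base = negative_bases()) {
  mode <- match.arg(mode)
  negative_base <- match.arg(negative_base)
  parts <- lapply(c("FAS", "pFAS", "ARND"), function(cat)
    estimate_prevalence(cascade, dx, cat, mode, negative_base))
  per_1000 <- sum(vapply(parts, `[[`, numeric(1), "per_1000"))
  new_prevalence_estimate("FASD_total", mode, per_1000, inputs = list(
    formula = "FAS + pFAS + ARND under identical mode and counts",
    components = stats::setNames(vapply(parts, `[[`, numeric(1), "per_1000"),
                                 c("FAS", "pFAS", "ARND")),
    negative_base = if (mode == "sensitivity") negative_base else NULL))
}

#' Dispatch a prevalence estimate by category and mode
#'
#' @inheritParams estimate_total
#' @param category one of [fasd_categories()].
#' @return a `prevalence_estimate`.
#' @export
estimate_prevalence <- function(cascade, dx, category,
                                mode = c("main", "sensitivity"),
                                negative_base = negative_bases()) {
  mode <- match.arg(mode)
  negative_base <- match.arg(negative_base)
  if (!category %in% fasd_categories())
    stop(sprintf("unknown category '%s'; valid: %s", category,
                 paste(fasd_categories(), collapse = ", ")), call. = FALSE)
  if (category == "FASD_total")
    return(estimate_total(cascade, dx, mode, negative_base))
  if (mode == "sensitivity")
    return(estimate_sensitivity(cascade, dx, category, negative_base))
  if (category == "FAS") estimate_fas(cascade, dx)
  else estimate_interview_category(cascade, dx, category)
}

#' All four category estimates as a table
#'
#' @inheritParams estimate_total
#' @return a `data.frame` with columns `category`, `mode`, `per_1000`
#'   (unrounded) and `per_1000_rendered` (one decimal, half-up).
#' @export
estimate_all <- function(cascade, dx, mode = c("main", "sensitivity"),
                         negative_base = negative_bases()) {
  mode <- match.arg(mode)
  negative_base <- match.arg(negative_base)
  ests <- lapply(fasd_categories(), function(cat)
    estimate_prevalence(cascade, dx, cat, mode, negative_base))
  data.frame(
    category = vapply(ests, `[[`, character(1), "category"),
    mode = mode,
    per_1000 = vapply(ests, `[[`, numeric(1), "per_1000"),
    per_1000_rendered = render_per_1000(
      vapply(ests, `[[`, numeric(1), "per_1000")),
    stringsAsFactors = FALSE)
}
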