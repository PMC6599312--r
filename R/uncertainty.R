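#' Monte Carlo settings for percentile confidence intervals
#'
#' @param n_reps number of simulated prevalence replicates (default
#'   100000, the scale used for the published intervals).
#' @param seed integer random seed.
#' @param ci_level coverage level in (0, 1).
#' @param resampling `"binomial"` resamples case counts k as
#'   Binomial(n, k/n) like every stage proportion; `"poisson_cases"`
#'   resamples case counts as Poisson(k) instead (stage proportions are
#'   always binomial).
#' @return an object of class `mc_settings`.
#' @export
mc_settings <- function(n_reps = 100000, seed = 1L, ci_level = 0.95,
                        resampling = c("binomial", "poisson_cases")) {
  resampling <- match.arg(resampling)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1)
    stop("n_reps must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1)
    stop("ci_level must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  structure(list(n_reps = as.integer(round(n_reps)), seed = as.integer(seed),
                 ci_level = ci_level, resampling = resampling),
            class = "mc_settings")
}

# internal: resample a proportion k/n as X/n, X ~ Binomial(n, k/n);
# degenerate cases (n = 0 handled upstream, k = 0 gives all zeros)
draw_proportions <- function(R, n, k) {
  stats::rbinom(R, n, k / n) / n
}

# internal: resample a case count per settings$resampling
draw_cases <- function(R, n, k, resampling) {
  if (resampling == "poisson_cases") stats::rpois(R, k)
  else stats::rbinom(R, n, k / n)
}

#' Simulate prevalence replicates
#'
#' Draws `n_reps` plug-in prevalence replicates by independently
#' resampling every stage proportion `k/n` as `X/n` with
#' `X ~ Binomial(n, k/n)`, resampling the case counts (binomial by
#' default, Poisson optional), and re-applying the plug-in estimator of
#' [estimate_prevalence()].
#'
#' All draws come from one generator seeded with `settings$seed` in a
#' fixed order — selection proportion, deficit proportion, FAS, pFAS,
#' ARND case counts, then (sensitivity mode) control-arm case counts
#' and the screen-negative fraction — and every vector is drawn
#' regardless of the requested category, so under a common seed all
#' categories (and the total) share identical stage draws and results
#' are bit-reproducible.
#'
#' @inheritParams estimate_total
#' @param category one of [fasd_categories()].
#' @param settings an [mc_settings] object.
#' @return numeric vector of per-1000 replicates, length
#'   `settings$n_reps`.
#' @export
simulate_prevalence_reps <- function(cascade, dx, category,
                                     mode = c("main", "sensitivity"),
                                     settings = mc_settings(),
                                     negative_base = negative_bases()) {
  mode <- match.arg(mode)
  negative_base <- match.arg(negative_base)
  stopifnot(inherits(settings, "mc_settings"))
  if (!category %in% fasd_categories())
    stop(sprintf("unknown category '%s'; valid: %s", category,
                 paste(fasd_categories(), collapse = ", ")), call. = FALSE)
  # same preconditions as the point estimators
  invisible(estimate_prevalence(cascade, dx, category, mode, negative_base))

  n1 <- stage_count(cascade, "phase1_assessed")
  n2a <- stage_count(cascade, "phase2_assessed")
  n_int <- stage_count(cascade, "interviewed")
  sel <- stage_count(cascade, "phase2_selected")
  def <- stage_count(cascade, "deficit2plus")
  R <- settings$n_reps

  set.seed(settings$seed)
  p_sel <- draw_proportions(R, n1, sel)
  p_def <- draw_proportions(R, n2a, def)
  x_fas <- draw_cases(R, n2a, dx$n_fas, settings$resampling)
  x_pfas <- if (n_int > 0) draw_cases(R, n_int, dx$n_pfas, settings$resampling)
            else rep(0, R)
  x_arnd <- if (n_int > 0) draw_cases(R, n_int, dx$n_arnd, settings$resampling)
            else rep(0, R)

  reps <- list(
    FAS = 1000 * p_sel * (x_fas / n2a),
    pFAS = if (n_int > 0) 1000 * p_sel * p_def * (x_pfas / n_int) else rep(0, R),
    ARND = if (n_int > 0) 1000 * p_sel * p_def * (x_arnd / n_int) else rep(0, R))

  if (mode == "sensitivity") {
    n_tdcc <- dx$n_tdcc_assessed
    n_neg <- negative_base_count(cascade, negative_base)
    x_tdcc <- lapply(c(FAS = "FAS", pFAS = "pFAS", ARND = "ARND"), function(cat)
      draw_cases(R, n_tdcc, dx$n_tdcc_cases[[cat]], settings$resampling))
    p_neg <- draw_proportions(R, n1, n_neg)  # one draw, shared by categories
    reps <- stats::setNames(lapply(names(reps), function(cat)
      reps[[cat]] + 1000 * (x_tdcc[[cat]] / n_tdcc) * p_neg), names(reps))
  }

  out <- if (category == "FASD_total") reps$FAS + reps$pFAS + reps$ARND
         else reps[[category]]
  out
}

#' Percentile confidence interval from replicates
#'
#' Empirical `(1-level)/2` and `1-(1-level)/2` quantiles under the
#' nearest-rank convention (the value at rank `ceiling(q * n)` of the
#' sorted replicates).
#'
#' @param reps numeric vector of replicates.
#' @param ci_level coverage level in (0, 1).
#' @return named numeric vector `c(low, high)`.
#' @export
#' @examples
#' percentile_ci(1:100, 0.95)  # c(low = 3, high = 98)
percentile_ci <- function(reps, ci_level = 0.95) {
  if (length(reps) == 0) stop("empty replicate vector", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must lie strictly between 0 and 1", call. = FALSE)
  srt <- sort(reps)
  n <- length(srt)
  alpha <- (1 - ci_level) / 2
  lo <- srt[max(1L, ceiling(alpha * n))]
  hi <- srt[min(n, ceiling((1 - alpha) * n))]
  c(low = lo, high = hi)
}

#' Point estimate with Monte Carlo percentile CI
#'
#' Convenience wrapper: computes the plug-in point estimate and
#' attaches the percentile CI of [simulate_prevalence_reps()].
#'
#' @inheritParams simulate_prevalence_reps
#' @return a `prevalence_estimate` with `ci_low`/`ci_high` populated.
#' @export
estimate_with_ci <- function(cascade, dx, category,
                             mode = c("main", "sensitivity"),
                             settings = mc_settings(),
                             negative_base = negative_bases()) {
  mode <- match.arg(mode)
  negative_base <- match.arg(negative_base)
  est <- estimate_prevalence(cascade, dx, category, mode, negative_base)
  reps <- simulate_prevalence_reps(cascade, dx, category, mode, settings,
                                   negative_base)
  ci <- percentile_ci(reps, settings$ci_level)
  est$ci_low <- unname(ci["low"])
  est$ci_high <- unname(ci["high"])
  est$inputs_digest$mc <- list(n_reps = settings$n_reps, seed = settings$seed,
                               ci_level = settings$ci_level,
                               resampling = settings$resampling)
  est
}
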