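#' Diagnostic categories
#'
#' @return the four estimable categories: the three diagnostic groups
#'   and their total.
#' @export
fasd_categories <- function() c("FAS", "pFAS", "ARND", "FASD_total")

#' Construct validated case-conference diagnostic counts
#'
#' Counts of suspected cases among case-conference-reviewed children,
#' plus the control-arm findings used by the screen-negative
#' sensitivity analysis: `n_tdcc_assessed` typically developing control
#' children (screen-negative children given the full assessment) and
#' the suspected cases found among them, per category.
#'
#' @param n_fas,n_pfas,n_arnd suspected case counts per category.
#' @param n_deferred deferred cases (confirmed prenatal alcohol
#'   exposure, insufficient impaired domains at assessment time).
#' @param n_tdcc_assessed control children completing the
#'   neurodevelopmental assessment.
#' @param n_tdcc_cases named vector of suspected cases found among the
#'   controls, one entry per category in `c("FAS","pFAS","ARND")`.
#' @param cascade optional linked [screening_cascade]; when supplied,
#'   the linkage invariant `n_fas + n_pfas + n_arnd <= n_interviewed`
#'   is enforced.
#' @return object of class `diagnosis_counts`.
#' @export
#' @examples
#' diagnosis_counts(n_fas = 3, n_pfas = 2, n_arnd = 16, n_deferred = 5,
#'                  n_tdcc_assessed = 84, n_tdcc_cases = c(ARND = 1))
diagnosis_counts <- function(n_fas, n_pfas, n_arnd, n_deferred = 0,
                             n_tdcc_assessed = 0,
                             n_tdcc_cases = c(FAS = 0, pFAS = 0, ARND = 0),
                             cascade = NULL) {
  tdcc <- c(FAS = 0, pFAS = 0, ARND = 0)
  if (length(n_tdcc_cases)) {
    bad <- setdiff(names(n_tdcc_cases), names(tdcc))
    if (length(bad) || is.null(names(n_tdcc_cases)))
      stop("n_tdcc_cases must be named with categories among FAS, pFAS, ARND",
           call. = FALSE)
    tdcc[names(n_tdcc_cases)] <- n_tdcc_cases
  }
  dx <- list(
    n_fas = check_count(n_fas, "n_fas"),
    n_pfas = check_count(n_pfas, "n_pfas"),
    n_arnd = check_count(n_arnd, "n_arnd"),
    n_deferred = check_count(n_deferred, "n_deferred"),
    n_tdcc_assessed = check_count(n_tdcc_assessed, "n_tdcc_assessed"),
    n_tdcc_cases = vapply(stats::setNames(names(tdcc), names(tdcc)),
                          function(k) check_count(tdcc[[k]],
                            paste0("n_tdcc_cases[", k, "]")), numeric(1))
  )
  if (sum(dx$n_tdcc_cases) > dx$n_tdcc_assessed)
    stop("total n_tdcc_cases exceeds n_tdcc_assessed", call. = FALSE)
  if (!is.null(cascade)) {
    stopifnot(inherits(cascade, "screening_cascade"))
    n_int <- stage_count(cascade, "interviewed")
    if (dx$n_fas + dx$n_pfas + dx$n_arnd > n_int)
      stop(sprintf("n_fas + n_pfas + n_arnd (%d) exceeds n_interviewed (%d)",
                   dx$n_fas + dx$n_pfas + dx$n_arnd, n_int), call. = FALSE)
  }
  structure(dx, class = "diagnosis_counts")
}

#' @export
print.diagnosis_counts <- function(x, ...) {
  cat("Case-conference diagnostic counts\n")
  cat(sprintf("  suspected FAS: %d, pFAS: %d, ARND: %d, deferred: %d\n",
              x$n_fas, x$n_pfas, x$n_arnd, x$n_deferred))
  cat(sprintf("  controls assessed: %d (cases among controls: %s)\n",
              x$n_tdcc_assessed,
              paste(names(x$n_tdcc_cases), x$n_tdcc_cases,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# internal: per-category case count accessor
dx_count <- function(dx, category) {
  switch(category,
         FAS = dx$n_fas, pFAS = dx$n_pfas, ARND = dx$n_arnd,
         stop(sprintf("unknown category '%s'; valid: FAS, pFAS, ARND", category),
              call. = FALSE))
}
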