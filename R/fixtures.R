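#' Available study fixtures
#'
#' @return character vector of fixture names.
#' @export
fixture_names <- function() {
  files <- list.files(system.file("extdata", package = "fasdprev"),
                      pattern = "^study_.*\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Load a bundled study fixture
#'
#' A fixture bundles the validated [screening_cascade],
#' [diagnosis_counts], the case/control 2x2 tables and the reported
#' reference values (per-1000 prevalences, CIs, stage percentages,
#' chi-square statistics) of the motivating screening study.
#'
#' Two fixtures ship with the package:
#' \describe{
#'   \item{study_text}{counts from the study narrative and flow diagram
#'     (793 selected / 762 assessed in Phase II) — the canonical set,
#'     which reproduces the printed FAS and pFAS estimates.}
#'   \item{study_table1}{the variant following the printed comparison
#'     table (817 eligible / 786 assessed); the study's Phase II totals
#'     are internally inconsistent between the two sources, so this
#'     variant is loaded with the consistency override flag and does
#'     not reproduce the printed estimates.}
#' }
#'
#' @param name fixture name, see [fixture_names()].
#' @return object of class `study_fixture`: list with `name`,
#'   `description`, `provenance`, `cascade`, `dx`, `tables` (named list
#'   of [two_by_two] with `reported_chi2` attributes) and `reported`.
#' @export
load_fixture <- function(name = "study_text") {
  known <- fixture_names()
  if (!name %in% known)
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(known, collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "fasdprev")
  raw <- yaml::read_yaml(path)

  cascade <- cascade_from_list(c(raw$cascade,
    list(allow_inconsistent = isTRUE(raw$allow_inconsistent))))
  dxl <- raw$diagnosis
  dx <- diagnosis_counts(
    n_fas = dxl$n_fas, n_pfas = dxl$n_pfas, n_arnd = dxl$n_arnd,
    n_deferred = dxl$n_deferred, n_tdcc_assessed = dxl$n_tdcc_assessed,
    n_tdcc_cases = unlist(dxl$n_tdcc_cases), cascade = cascade)

  tables <- lapply(raw$tables, function(tb) {
    t <- two_by_two(tb$a, tb$b, tb$c, tb$d)
    attr(t, "reported_chi2") <- tb$reported_chi2
    t
  })

  structure(list(name = raw$name, description = raw$description,
                 provenance = raw$provenance, cascade = cascade, dx = dx,
                 tables = tables, reported = raw$reported),
            class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf("Study fixture '%s'\n", x$name))
  cat(strwrap(x$description, indent = 2, exdent = 2), sep = "\n")
  print(x$cascade)
  print(x$dx)
  invisible(x)
}
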