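#' Stage names of the screening cascade
#'
#' The fixed enumeration of recruitment/screening stages, in flow order.
#' `cbcl` is a side branch: its parent stage is `deficit2plus`, the same
#' as `interviewed`.
#'
#' @return character vector of valid stage names.
#' @export
cascade_stages <- function() {
  c("invited", "responded", "consented", "phase1_assessed",
    "phase2_selected", "phase2_assessed", "deficit2plus",
    "interviewed", "cbcl")
}

# parent of each stage, used for proportion-of-previous-stage columns
stage_parent <- function() {
  c(invited = NA, responded = "invited", consented = "responded",
    phase1_assessed = "consented", phase2_selected = "phase1_assessed",
    phase2_assessed = "phase2_selected", deficit2plus = "phase2_assessed",
    interviewed = "deficit2plus", cbcl = "deficit2plus")
}

#' Construct a validated screening cascade
#'
#' Holds the integer counts at every node of a multi-phase
#' screening/recruitment flow: consent forms distributed, parental
#' responses and consents, Phase I assessments (growth, dysmorphology,
#' behavioural/learning history), selection into Phase II, completion of
#' the neurodevelopmental assessment, the two-plus-domain deficit
#' threshold, maternal interviews, and parent/guardian behaviour
#' checklists (CBCL).
#'
#' Counts must be non-negative integers and weakly decreasing along the
#' flow.  The two Phase II ordering constraints
#' (`n_phase2_selected <= n_phase1_assessed` and
#' `n_phase2_assessed <= n_phase2_selected`) can be relaxed with
#' `allow_inconsistent = TRUE`, which accommodates published count
#' tables whose Phase II totals disagree between text and tables; a
#' relaxed violation is reported via [message()] so it is always logged.
#'
#' @param n_invited consent forms distributed (children).
#' @param n_responded parent/guardian responses.
#' @param n_consented consents given.
#' @param n_phase1_assessed children completing Phase I.
#' @param n_phase2_selected children selected to proceed to Phase II.
#' @param n_phase2_assessed children completing the neurodevelopmental
#'   assessment.
#' @param n_deficit2plus children with deficits in two or more
#'   neurodevelopmental domains.
#' @param n_interviewed completed biological-mother interviews.
#' @param n_cbcl completed parent/guardian behaviour checklists.
#' @param allow_inconsistent relax the two Phase II ordering invariants
#'   (logged).
#' @return an object of class `screening_cascade` (named numeric vector
#'   of counts with an `allow_inconsistent` attribute).
#' @export
#' @examples
#' casc <- screening_cascade(
#'   n_invited = 8209, n_responded = 3854, n_consented = 2693,
#'   n_phase1_assessed = 2555, n_phase2_selected = 793,
#'   n_phase2_assessed = 762, n_deficit2plus = 323,
#'   n_interviewed = 132, n_cbcl = 136)
#' stage_proportion(casc, "phase2_selected", "phase1_assessed")
screening_cascade <- function(n_invited, n_responded, n_consented,
                              n_phase1_assessed, n_phase2_selected,
                              n_phase2_assessed, n_deficit2plus,
                              n_interviewed, n_cbcl,
                              allow_inconsistent = FALSE) {
  counts <- c(
    invited = check_count(n_invited, "n_invited"),
    responded = check_count(n_responded, "n_responded"),
    consented = check_count(n_consented, "n_consented"),
    phase1_assessed = check_count(n_phase1_assessed, "n_phase1_assessed"),
    phase2_selected = check_count(n_phase2_selected, "n_phase2_selected"),
    phase2_assessed = check_count(n_phase2_assessed, "n_phase2_assessed"),
    deficit2plus = check_count(n_deficit2plus, "n_deficit2plus"),
    interviewed = check_count(n_interviewed, "n_interviewed"),
    cbcl = check_count(n_cbcl, "n_cbcl")
  )

  strict <- list(
    c("responded", "invited"), c("consented", "responded"),
    c("phase1_assessed", "consented"), c("deficit2plus", "phase2_assessed"),
    c("interviewed", "deficit2plus"), c("cbcl", "deficit2plus")
  )
  relaxable <- list(
    c("phase2_selected", "phase1_assessed"),
    c("phase2_assessed", "phase2_selected")
  )
  for (pair in strict) {
    if (counts[pair[1]] > counts[pair[2]])
      stop(sprintf("cascade invariant violated: n_%s (%d) > n_%s (%d)",
                   pair[1], counts[pair[1]], pair[2], counts[pair[2]]),
           call. = FALSE)
  }
  for (pair in relaxable) {
    if (counts[pair[1]] > counts[pair[2]]) {
      if (!allow_inconsistent)
        stop(sprintf(paste0("cascade invariant violated: n_%s (%d) > n_%s (%d); ",
                            "set allow_inconsistent = TRUE to keep these counts"),
                     pair[1], counts[pair[1]], pair[2], counts[pair[2]]),
             call. = FALSE)
      message(sprintf("screening_cascade: inconsistent counts kept (n_%s = %d > n_%s = %d)",
                      pair[1], counts[pair[1]], pair[2], counts[pair[2]]))
    }
  }

  structure(counts, class = "screening_cascade",
            allow_inconsistent = allow_inconsistent)
}

#' @export
print.screening_cascade <- function(x, ...) {
  cat("Multi-phase screening cascade\n")
  rep <- cascade_report(x)
  print.data.frame(rep, row.names = FALSE, right = FALSE)
  invisible(x)
}

# internal accessor with error on unknown stage
stage_count <- function(cascade, stage) {
  if (!stage %in% cascade_stages())
    stop(sprintf("unknown stage '%s'; valid stages: %s", stage,
                 paste(cascade_stages(), collapse = ", ")), call. = FALSE)
  unname(cascade[[stage]])
}

#' Proportion of one cascade stage relative to another
#'
#' Returns the exact ratio `count(numerator) / count(denominator)`.
#' Render with [percent()] for one-decimal half-up display, e.g. the
#' proportion of Phase-I-assessed children selected for Phase II.
#'
#' @param cascade a [screening_cascade].
#' @param numerator_stage,denominator_stage stage names (see
#'   [cascade_stages()]).
#' @return a proportion (numeric scalar).
#' @export
#' @examples
#' casc <- screening_cascade(8209, 3854, 2693, 2555, 793, 762, 323, 132, 136)
#' percent(stage_proportion(casc, "phase2_selected", "phase1_assessed")) # "31.0%"
stage_proportion <- function(cascade, numerator_stage, denominator_stage) {
  stopifnot(inherits(cascade, "screening_cascade"))
  num <- stage_count(cascade, numerator_stage)
  den <- stage_count(cascade, denominator_stage)
  if (den == 0)
    stop(sprintf("denominator stage '%s' has zero count", denominator_stage),
         call. = FALSE)
  num / den
}

#' Tabulate the whole cascade
#'
#' One row per stage in flow order: count, proportion of the parent
#' stage, and proportion of the Phase I assessed population (the
#' denominator of all prevalence estimates; `NA` for stages upstream of
#' it).  The product of `prop_of_previous` along the main chain
#' (excluding the `cbcl` side branch) telescopes to
#' `interviewed / invited`.
#'
#' @param cascade a [screening_cascade].
#' @return a `data.frame` with columns `stage`, `count`, `denominator`,
#'   `prop_of_previous`, `percent_of_previous`, `prop_of_phase1`.
#' @seealso [report_json()] and [report_tsv()] for serialization.
#' @export
cascade_report <- function(cascade) {
  stopifnot(inherits(cascade, "screening_cascade"))
  stages <- cascade_stages()
  parents <- stage_parent()
  n1 <- stage_count(cascade, "phase1_assessed")
  rows <- lapply(stages, function(s) {
    p <- parents[[s]]
    prop <- if (is.na(p)) NA_real_ else
      stage_count(cascade, s) / stage_count(cascade, p)
    after_p1 <- match(s, stages) >= match("phase1_assessed", stages)
    data.frame(
      stage = s,
      count = stage_count(cascade, s),
      denominator = if (is.na(p)) NA_character_ else p,
      prop_of_previous = prop,
      percent_of_previous = if (is.na(prop)) NA_character_ else percent(prop),
      prop_of_phase1 = if (after_p1 && n1 > 0) stage_count(cascade, s) / n1
                       else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Serialize a cascade report to JSON
#'
#' @param report a data.frame from [cascade_report()].
#' @return a JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(report, dataframe = "rows", na = "null",
                                auto_unbox = TRUE, digits = NA))
}

#' Serialize a cascade report to tab-separated text
#'
#' @param report a data.frame from [cascade_report()].
#' @param path optional file path; if `NULL` the TSV is returned as a
#'   character string.
#' @return the path (invisibly) or a TSV string.
#' @export
report_tsv <- function(report, path = NULL) {
  if (is.null(path)) {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a screening cascade as a config file
#'
#' The config is a flat mapping with exactly the `n_*` field names of
#' [screening_cascade()] (YAML or JSON, chosen by file extension), plus
#' an optional `allow_inconsistent` flag.  A two-column CSV layout
#' (`stage,count`, stage names without the `n_` prefix) is also
#' accepted by [read_cascade_csv()].
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return [read_cascade()] returns a `screening_cascade`;
#'   [write_cascade()] returns `path` invisibly.
#' @export
read_cascade <- function(path) {
  cfg <- read_config_file(path)
  cascade_from_list(cfg)
}

#' @rdname read_cascade
#' @param cascade a [screening_cascade] to write.
#' @export
write_cascade <- function(cascade, path) {
  stopifnot(inherits(cascade, "screening_cascade"))
  lst <- as.list(stats::setNames(as.numeric(cascade),
                                 paste0("n_", names(cascade))))
  lst$allow_inconsistent <- isTRUE(attr(cascade, "allow_inconsistent"))
  write_config_file(lst, path)
  invisible(path)
}

#' @rdname read_cascade
#' @export
read_cascade_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("stage", "count") %in% names(df)))
    stop("cascade CSV must have columns 'stage' and 'count'", call. = FALSE)
  lst <- as.list(stats::setNames(df$count, paste0("n_", df$stage)))
  cascade_from_list(lst)
}

# internal: build a cascade from a named list of n_* fields
cascade_from_list <- function(lst) {
  fields <- paste0("n_", cascade_stages())
  missing <- setdiff(fields, names(lst))
  if (length(missing))
    stop("cascade config missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(screening_cascade, c(lst[fields],
    list(allow_inconsistent = isTRUE(lst$allow_inconsistent))))
}

# internal config IO helpers (format by extension)
read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext, " (use YAML or JSON)",
            call. = FALSE)
}

write_config_file <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json") jsonlite::write_json(x, path, auto_unbox = TRUE,
                                               digits = NA, pretty = TRUE)
  else stop("unsupported config format: .", ext, " (use YAML or JSON)",
            call. = FALSE)
  invisible(path)
}
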