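#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used for all rendered
#' percentages and per-1000 rates (base [round()] rounds half to even,
#' which does not reproduce conventionally printed epidemiological
#' tables).  A nudge of 1e-9 absorbs binary representation error in
#' values such as 1.9999999999 that are exact decimals in intent.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(2.5)      # 3, not 2
#' round_half_up(0.42388 * 100, 1)  # 42.4
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Format a proportion as a percentage string
#'
#' @param p proportion in \[0, 1\].
#' @param digits decimal places (default 1, half-up).
#' @return character vector like `"31.0%"`.
#' @export
percent <- function(p, digits = 1) {
  paste0(formatC(round_half_up(100 * p, digits), format = "f", digits = digits), "%")
}

#' Render a per-1000 rate to one decimal
#'
#' @param x per-1000 rate.
#' @param digits decimal places (default 1, half-up).
#' @return numeric, rounded half-up.
#' @export
render_per_1000 <- function(x, digits = 1) {
  round_half_up(x, digits)
}

# internal: integer-valued, non-negative scalar check
check_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < 0) stop(sprintf("'%s' must be >= 0 (got %s)", name, x), call. = FALSE)
  if (abs(x - round(x)) > 1e-8)
    stop(sprintf("'%s' must be integer-valued (got %s)", name, x), call. = FALSE)
  as.numeric(round(x))
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  x
}
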