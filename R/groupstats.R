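#' A 2x2 contingency table
#'
#' Rows are the two groups (e.g. suspected cases vs controls), columns
#' trait present/absent.
#'
#' @param a,b first-group counts (trait present, trait absent).
#' @param c,d second-group counts (trait present, trait absent).
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  t <- c(a = check_count(a, "a"), b = check_count(b, "b"),
         c = check_count(c, "c"), d = check_count(d, "d"))
  if (sum(t) == 0) stop("table total must be > 0", call. = FALSE)
  structure(as.list(t), class = "two_by_two")
}

#' Pearson chi-square for a 2x2 table, no continuity correction
#'
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of
#' freedom.  The Yates continuity correction is deliberately never
#' applied.
#'
#' @param t a [two_by_two] table.
#' @return list with `statistic`, `df` (1) and `p_value`.
#' @export
#' @examples
#' # height at/below 10th percentile: 5/21 cases vs 2/83 controls
#' pearson_chi2(two_by_two(5, 16, 2, 81))$statistic  # 12.226
pearson_chi2 <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  margins <- c("a+b" = a + b, "c+d" = c + d, "a+c" = a + c, "b+d" = b + d)
  if (any(margins == 0))
    stop("chi-square undefined: zero margin (",
         paste(names(margins)[margins == 0], collapse = ", "), ")",
         call. = FALSE)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-group summary statistics
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  n <- check_count(n, "n")
  if (n < 2) stop("group n must be >= 2", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Pooled-variance two-sample t statistic from summary statistics
#'
#' `t = (mean1 - mean2) / (sp * sqrt(1/n1 + 1/n2))` with the pooled
#' variance `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`;
#' sign convention group1 minus group2.
#'
#' @param g1,g2 [group_summary] objects.
#' @return list with `statistic`, `df` and `p_value` (two-sided).
#' @export
pooled_t <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  if (sp2 == 0) {
    if (g1$mean == g2$mean)
      return(list(statistic = 0, df = df, p_value = 1))
    stop("pooled SD is zero with unequal means: t statistic is infinite",
         call. = FALSE)
  }
  stat <- (g1$mean - g2$mean) / (sqrt(sp2) * sqrt(1 / g1$n + 1 / g2$n))
  list(statistic = stat, df = df,
       p_value = 2 * stats::pt(abs(stat), df, lower.tail = FALSE))
}

#' One-way ANOVA F statistic from summary statistics
#'
#' Between/within mean squares reconstructed from per-group `n`, mean
#' and SD.  Degenerate input with zero between- and within-group
#' variance yields `F = 0`.
#'
#' @param groups list of [group_summary] objects (length >= 2).
#' @return list with `statistic`, `df1`, `df2`, `p_value`, and `msw`
#'   (within mean square, reused by [tukey_hsd()]).
#' @export
oneway_anova <- function(groups) {
  stopifnot(length(groups) >= 2,
            all(vapply(groups, inherits, logical(1), "group_summary")))
  ns <- vapply(groups, `[[`, numeric(1), "n")
  ms <- vapply(groups, `[[`, numeric(1), "mean")
  sds <- vapply(groups, `[[`, numeric(1), "sd")
  k <- length(groups); N <- sum(ns)
  grand <- sum(ns * ms) / N
  ssb <- sum(ns * (ms - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  stat <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  list(statistic = stat, df1 = df1, df2 = df2,
       p_value = stats::pf(stat, df1, df2, lower.tail = FALSE), msw = msw)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' For each pair `q = |mean_i - mean_j| / sqrt(MSW (1/n_i + 1/n_j) / 2)`
#' compared against the studentized-range critical value at
#' `(k, N - k)` degrees of freedom.
#'
#' @param groups list of [group_summary] objects.
#' @param alpha familywise significance level.
#' @param names optional group labels.
#' @return a `data.frame` with one row per pair: `group_i`, `group_j`,
#'   `diff`, `q`, `critical`, `p_value`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05, names = NULL) {
  aov_res <- oneway_anova(groups)
  k <- length(groups); df2 <- aov_res$df2
  if (is.null(names)) names <- paste0("group", seq_len(k))
  crit <- stats::qtukey(1 - alpha, k, df2)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    gi <- groups[[ij[1]]]; gj <- groups[[ij[2]]]
    diff <- gi$mean - gj$mean
    se <- sqrt(aov_res$msw * (1 / gi$n + 1 / gj$n) / 2)
    q <- if (se == 0) { if (diff == 0) 0 else Inf } else abs(diff) / se
    data.frame(group_i = names[ij[1]], group_j = names[ij[2]],
               diff = diff, q = q, critical = crit,
               p_value = stats::ptukey(q, k, df2, lower.tail = FALSE),
               significant = q > crit, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
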