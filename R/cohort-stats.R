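#' Uncorrected Pearson chi-square for a 2x2 table
#'
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree of
#' freedom, with no Yates continuity correction (the convention that
#' reproduces SPSS's printed "Pearson Chi-Square" row).
#'
#' @param t A [two_by_two()] table.
#' @return List with `statistic`, `df` (always 1) and `p`.
#' @export
#' @examples
#' pearson_chi2(two_by_two(24, 60, 61, 54))
pearson_chi2 <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop_validation("zero margin: chi-square undefined")
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Two-sample t test
#'
#' Student's pooled-variance two-sample t by default (the SPSS-default
#' row reported in cohort tables); Welch's unequal-variance form via
#' `var_equal = FALSE`. Two-sided p.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `statistic`, `df`, `p`.
#' @export
students_t <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_validation("each group needs n >= 2")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 <= 0) stop_validation("zero pooled variance")
    stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 <= 0) stop_validation("zero variance")
    stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(statistic = stat, df = df, p = 2 * stats::pt(-abs(stat), df))
}

#' Pooled t from group summaries
#'
#' Student's t computed from (mean, SD, n) per group -- what a reader can
#' recompute from a printed "mean +/- SD" table row.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `statistic`, `df`, `p`.
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop_validation("each group needs n >= 2")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_validation("zero pooled variance")
  stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = stat, df = df, p = 2 * stats::pt(-abs(stat), df))
}

#' Mann-Whitney rank-sum test
#'
#' Rank-sum U with normal approximation and tie correction; two-sided p.
#' The z statistic is negative when `x` is stochastically smaller than
#' `y` (the fixed group ordering used in cohort tables, where the
#' low-score group is listed first). With `exact = TRUE` and no ties, the
#' exact two-sided p is computed from the null U distribution instead.
#'
#' @param x,y Numeric samples.
#' @param exact Use the exact null distribution (small samples, no ties).
#' @return List with `U`, `z`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop_validation("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(all_v)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  has_ties <- any(ties > 1)
  if (exact && !has_ties) {
    p <- if (u == mu) 1 else {
      lo <- min(u, n1 * n2 - u)
      min(1, 2 * stats::pwilcox(lo, n1, n2))
    }
    method <- "exact"
  } else {
    if (exact) warning("ties present; falling back to normal approximation",
                       call. = FALSE)
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal_tie_corrected"
  }
  list(U = u, z = z, p = p, method = method)
}

.fmt_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
.fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.1f(%.1f-%.1f)", q[2], q[1], q[3])
}
.fmt_rate <- function(events, trials) {
  sprintf("%d/%d(%.1f)", events, trials, 100 * events / trials)
}

#' Two-group comparison battery
#'
#' Builds the classical cohort-comparison table: one row per variable,
#' with total and per-group summaries, the test statistic and the
#' two-sided p. Routing is declared per variable, mirroring how such
#' tables mark normally distributed rows (t test, mean +/- SD),
#' non-normal rows (Mann-Whitney z, median(IQR)) and rate rows
#' (uncorrected Pearson chi-square, events/trials(%)). Percentages are
#' always recomputed from numerators and denominators, never read from
#' input.
#'
#' @param cohort Data frame with one row per patient.
#' @param group Name of a column in `cohort`; must be binary. Rows are
#'   compared as (low group) vs (high group) by sorted group value.
#' @param variables List of per-variable declarations, each a list with
#'   `var` (column name), `type` (`"normal"`, `"nonnormal"` or `"rate"`),
#'   optional `label`, and for rates an optional `den` column: when `den`
#'   is `NULL` the variable is a per-patient 0/1 event (denominator =
#'   patients); otherwise `var` counts events and `den` counts trials per
#'   patient (e.g. implantations per embryo transferred).
#' @return A data frame of class `comparison_table` with columns
#'   `variable`, `type`, `total`, `group_low`, `group_high`, `statistic`,
#'   `p`; skipped variables (missing columns) are dropped with a warning.
#' @export
#' @examples
#' cohort <- data.frame(g = rep(0:1, each = 40),
#'                      age = rnorm(80, 32, 4),
#'                      preg = rbinom(80, 1, 0.4))
#' comparison_table(cohort, "g",
#'   list(list(var = "age", type = "normal"),
#'        list(var = "preg", type = "rate")))
comparison_table <- function(cohort, group, variables) {
  if (!group %in% names(cohort)) stop_validation("grouping column not found")
  g <- cohort[[group]]
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    stop_validation("grouping variable must take exactly two values")
  }
  lo <- cohort[g == lev[1], , drop = FALSE]
  hi <- cohort[g == lev[2], , drop = FALSE]
  rows <- lapply(variables, function(v) {
    type <- match.arg(v$type, c("normal", "nonnormal", "rate"))
    need <- c(v$var, if (type == "rate") v$den)
    if (!all(need %in% names(cohort))) {
      warning(sprintf("variable '%s' missing from cohort; row skipped", v$var),
              call. = FALSE)
      return(NULL)
    }
    label <- v$label %||% v$var
    if (type == "rate") {
      ev <- function(d) sum(d[[v$var]])
      tr <- function(d) if (is.null(v$den)) nrow(d) else sum(d[[v$den]])
      tab <- two_by_two(ev(lo), tr(lo) - ev(lo), ev(hi), tr(hi) - ev(hi))
      # chi-square is invariant to which group is labelled "index positive"
      ct <- pearson_chi2(tab)
      data.frame(variable = label, type = type,
                 total = .fmt_rate(ev(lo) + ev(hi), tr(lo) + tr(hi)),
                 group_low = .fmt_rate(ev(lo), tr(lo)),
                 group_high = .fmt_rate(ev(hi), tr(hi)),
                 statistic = ct$statistic, p = ct$p,
                 stringsAsFactors = FALSE)
    } else if (type == "normal") {
      tt <- students_t(lo[[v$var]], hi[[v$var]])
      data.frame(variable = label, type = type,
                 total = .fmt_mean_sd(cohort[[v$var]]),
                 group_low = .fmt_mean_sd(lo[[v$var]]),
                 group_high = .fmt_mean_sd(hi[[v$var]]),
                 statistic = tt$statistic, p = tt$p,
                 stringsAsFactors = FALSE)
    } else {
      mw <- mann_whitney(lo[[v$var]], hi[[v$var]])
      data.frame(variable = label, type = type,
                 total = .fmt_median_iqr(cohort[[v$var]]),
                 group_low = .fmt_median_iqr(lo[[v$var]]),
                 group_high = .fmt_median_iqr(hi[[v$var]]),
                 statistic = mw$z, p = mw$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_validation("no usable variables in declaration list")
  class(out) <- c("comparison_table", class(out))
  attr(out, "group") <- group
  attr(out, "n") <- c(low = nrow(lo), high = nrow(hi))
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("Comparison by '%s' (n = %d vs %d)\n",
              attr(x, "group"), n[["low"]], n[["high"]]))
  y <- as.data.frame(x)
  y$statistic <- sprintf("%.3f", y$statistic)
  y$p <- sprintf("%.3f", y$p)
  print(y, row.names = FALSE, right = FALSE)
  invisible(x)
}
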