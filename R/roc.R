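#' 2x2 classification table
#'
#' Counts of index-positive/negative by outcome-positive/negative:
#' `a` = index+ outcome+, `b` = index+ outcome-, `c` = index- outcome+,
#' `d` = index- outcome-.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class `two_by_two`.
#' @export
#' @examples
#' sens_spec(two_by_two(61, 54, 24, 60))
two_by_two <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop_validation("counts a, b, c, d must be non-negative integers")
  }
  structure(as.list(as.integer(x)) |> stats::setNames(c("a", "b", "c", "d")),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(index = c("positive", "negative"),
                              outcome = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of a 2x2 table
#'
#' `sens = a / (a + c)`, `spec = d / (b + d)`; the Youden index
#' `J = sens + spec - 1` is returned alongside.
#'
#' @param t A [two_by_two()] table.
#' @return List with `sens`, `spec`, `youden_j`.
#' @export
sens_spec <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$a + t$c == 0L || t$b + t$d == 0L) {
    stop_validation("zero outcome margin: sensitivity/specificity undefined")
  }
  sens <- t$a / (t$a + t$c)
  spec <- t$d / (t$b + t$d)
  list(sens = sens, spec = spec, youden_j = sens + spec - 1)
}

.check_index_outcome <- function(index, outcome, direction) {
  if (length(index) != length(outcome)) {
    stop_validation("`index` and `outcome` lengths differ")
  }
  outcome <- as.logical(outcome)
  if (anyNA(index) || anyNA(outcome)) stop_validation("missing values in input")
  if (!any(outcome) || all(outcome)) {
    stop_validation("need at least one positive and one negative outcome")
  }
  direction <- match.arg(direction, c("higher_is_positive", "lower_is_positive"))
  list(index = as.numeric(index), outcome = outcome, direction = direction)
}

#' Empirical ROC curve
#'
#' One operating point per distinct observed index value plus the two
#' trivial endpoints; each point is the (sensitivity, specificity) of the
#' rule "positive if index >= t" (or "<= t" when
#' `direction = "lower_is_positive"`).
#'
#' @param index Numeric prognostic index (e.g. EFI total, r-AFS stage).
#' @param outcome Logical (or 0/1) outcome, e.g. clinical pregnancy.
#' @param direction `"higher_is_positive"` (default) or
#'   `"lower_is_positive"`.
#' @return Data frame with columns `threshold` (on the original index
#'   scale; `-Inf`/`Inf` mark the all-positive/all-negative endpoints),
#'   `sens`, `spec`.
#' @export
empirical_roc <- function(index, outcome,
                          direction = "higher_is_positive") {
  z <- .check_index_outcome(index, outcome, direction)
  x <- if (z$direction == "higher_is_positive") z$index else -z$index
  pos <- x[z$outcome]; neg <- x[!z$outcome]
  thr <- c(-Inf, sort(unique(x)), Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  threshold <- if (z$direction == "higher_is_positive") thr else -thr
  data.frame(threshold = threshold, sens = sens, spec = spec)
}

# trapezoidal area under the (1 - spec, sens) polyline
.roc_trapezoid_area <- function(curve) {
  fpr <- 1 - curve$spec
  ord <- order(fpr, curve$sens)
  fpr <- fpr[ord]; tpr <- curve$sens[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Mann-Whitney AUC
#'
#' AUC = (concordant pairs + half the tied pairs) / (n_pos * n_neg),
#' computed from midranks; identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @inheritParams empirical_roc
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(index, outcome,
                             direction = "higher_is_positive") {
  z <- .check_index_outcome(index, outcome, direction)
  x <- if (z$direction == "higher_is_positive") z$index else -z$index
  np <- sum(z$outcome); nn <- sum(!z$outcome)
  r <- rank(x)
  (sum(r[z$outcome]) - np * (np + 1) / 2) / (np * nn)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `SE^2 = (A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) / (n_pos n_neg)`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc Estimated AUC, strictly inside (0, 1).
#' @param n_pos,n_neg Numbers of outcome-positive / -negative patients.
#' @return Standard error (positive real).
#' @export
auc_se_hanley_mcneil <- function(auc, n_pos, n_neg) {
  if (!is.finite(auc) || auc <= 0 || auc >= 1) {
    stop_validation("Hanley-McNeil SE needs 0 < auc < 1")
  }
  if (n_pos < 1 || n_neg < 1) stop_validation("degenerate group counts")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Bootstrap standard error of an AUC
#'
#' Stratified nonparametric bootstrap: positives and negatives are
#' resampled separately with replacement, the Mann-Whitney AUC recomputed,
#' and the SD over replicates returned.
#'
#' @inheritParams empirical_roc
#' @param reps Number of bootstrap replicates.
#' @param seed Optional integer seed (local to this call).
#' @return Standard error (positive real).
#' @export
auc_se_bootstrap <- function(index, outcome, direction = "higher_is_positive",
                             reps = 2000L, seed = NULL) {
  z <- .check_index_outcome(index, outcome, direction)
  x <- if (z$direction == "higher_is_positive") z$index else -z$index
  pos <- x[z$outcome]; neg <- x[!z$outcome]
  np <- length(pos); nn <- length(neg)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  aucs <- vapply(seq_len(reps), function(i) {
    p <- sample(pos, np, replace = TRUE)
    n <- sample(neg, nn, replace = TRUE)
    r <- rank(c(p, n))
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  }, numeric(1))
  stats::sd(aucs)
}

#' Wald confidence interval and test against AUC = 0.5
#'
#' CI = `auc +/- z * se` on the probability scale, clipped to \[0, 1\];
#' two-sided normal p-value for `(auc - 0.5) / se`.
#'
#' @param auc Estimated AUC.
#' @param se Its standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return List with `ci` (length-2 numeric) and `p_vs_half`.
#' @export
auc_ci_test <- function(auc, se, level = 0.95) {
  if (!is.finite(se) || se <= 0) stop_validation("`se` must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  p <- 2 * stats::pnorm(-abs((auc - 0.5) / se))
  list(ci = ci, p_vs_half = p)
}

#' Youden-optimal operating point
#'
#' Selects the threshold maximizing J = sens + spec - 1 over the finite
#' operating points of an empirical ROC curve. The cut-off is reported as
#' the smallest index value classified positive; ties in J are broken
#' toward higher sensitivity, then toward the lower cut-off.
#'
#' @param roc A curve from [empirical_roc()] (or a `roc_analysis`).
#' @return List with `cutoff`, `sens`, `spec`, `youden_j`.
#' @export
youden_optimal <- function(roc) {
  if (inherits(roc, "roc_analysis")) roc <- roc$curve
  fin <- roc[is.finite(roc$threshold), , drop = FALSE]
  if (!nrow(fin)) stop_validation("no finite operating points")
  j <- fin$sens + fin$spec - 1
  cand <- fin[j == max(j), , drop = FALSE]
  cand <- cand[cand$sens == max(cand$sens), , drop = FALSE]
  best <- cand[which.min(cand$threshold), ]
  list(cutoff = best$threshold, sens = best$sens, spec = best$spec,
       youden_j = best$sens + best$spec - 1)
}

#' Full ROC analysis of a prognostic index
#'
#' Computes the empirical ROC curve, the Mann-Whitney AUC (equal to the
#' trapezoidal area under the curve), its standard error (Hanley-McNeil
#' by default, stratified bootstrap on request), a Wald 95% CI clipped to
#' \[0, 1\], a two-sided normal test against AUC = 0.5, and the
#' Youden-optimal cut-off.
#'
#' @inheritParams empirical_roc
#' @param se_method `"hanley"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `se_method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @param level Confidence level.
#' @return An object of class `roc_analysis`.
#' @export
#' @examples
#' set.seed(1)
#' idx <- c(rpois(40, 7), rpois(60, 5))
#' out <- rep(c(TRUE, FALSE), c(40, 60))
#' roc_analysis(idx, out)
roc_analysis <- function(index, outcome, direction = "higher_is_positive",
                         se_method = c("hanley", "bootstrap"),
                         boot_reps = 2000L, seed = NULL, level = 0.95) {
  se_method <- match.arg(se_method)
  z <- .check_index_outcome(index, outcome, direction)
  curve <- empirical_roc(index, outcome, direction = z$direction)
  auc <- auc_mann_whitney(index, outcome, direction = z$direction)
  n_pos <- sum(z$outcome); n_neg <- sum(!z$outcome)
  se <- if (se_method == "hanley") {
    # degenerate AUC of exactly 0 or 1 has no Hanley-McNeil SE; nudge inward
    auc_se_hanley_mcneil(min(max(auc, 1 / (2 * n_pos * n_neg)),
                             1 - 1 / (2 * n_pos * n_neg)), n_pos, n_neg)
  } else {
    auc_se_bootstrap(index, outcome, direction = z$direction,
                     reps = boot_reps, seed = seed)
  }
  ct <- auc_ci_test(auc, se, level = level)
  yj <- youden_optimal(curve)
  structure(list(curve = curve, auc = auc, se = se, se_method = se_method,
                 ci95 = ct$ci, p_vs_half = ct$p_vs_half,
                 youden_cutoff = yj$cutoff, youden_sens = yj$sens,
                 youden_spec = yj$spec, youden_j = yj$youden_j,
                 n_pos = n_pos, n_neg = n_neg, direction = z$direction,
                 level = level),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("ROC analysis (%d positive / %d negative, %s)\n",
              x$n_pos, x$n_neg, x$direction))
  cat(sprintf("  AUC = %.*f, SE = %.*f (%s), %d%% CI = %.*f-%.*f, P = %.3g\n",
              digits, x$auc, digits, x$se, x$se_method,
              round(100 * x$level), digits, x$ci95[1], digits, x$ci95[2],
              x$p_vs_half))
  cat(sprintf("  Youden cut-off %s %g: sens = %.1f%%, spec = %.1f%%, J = %.*f\n",
              if (x$direction == "higher_is_positive") ">=" else "<=",
              x$youden_cutoff, 100 * x$youden_sens, 100 * x$youden_spec,
              digits, x$youden_j))
  invisible(x)
}
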