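#' Sample size for a paired diagnostic-accuracy design
#'
#' Plans the number of patients needed to compare two binary classifiers
#' applied to the same subjects against a common gold standard (a
#' McNemar-type paired-proportions design), from a pilot 2x2 cross
#' table of the two classifications. With `p1 = (a+b)/N` (rate positive
#' by the first rule), `p2 = (a+c)/N` (rate positive by the second),
#' `p = a/N` (both positive), difference `d = p1 - p2` and discordant
#' mass `psi = p1 + p2 - 2p` (`= 2 * pbar`):
#'
#' \deqn{n = \left\lceil \frac{\left(z_{1-\alpha/2}\sqrt{\psi} +
#'   z_{1-\beta}\sqrt{\psi - d^2}\right)^2}{d^2} \right\rceil}
#'
#' z-quantiles are used at full double precision and the result is
#' rounded up to an integer.
#'
#' @param pilot A [two_by_two()] pilot table (`a` = positive by both).
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @param power Target power `1 - beta` (default 0.90).
#' @return An object of class `sample_size` carrying `n` and every
#'   intermediate quantity (`p1`, `p2`, `p`, `pbar`, `d`, `psi`,
#'   `z_alpha`, `z_beta`, `n_raw`).
#' @export
#' @examples
#' sample_size_paired(two_by_two(44, 47, 23, 47))
sample_size_paired <- function(pilot, alpha = 0.05, power = 0.90) {
  stopifnot(inherits(pilot, "two_by_two"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("`alpha` must lie in (0, 1)")
  }
  if (!is.finite(power) || power <= 0 || power >= 1) {
    stop_validation("`power` must lie in (0, 1)")
  }
  n_tot <- pilot$a + pilot$b + pilot$c + pilot$d
  if (n_tot == 0L) stop_validation("empty pilot table")
  p1 <- (pilot$a + pilot$b) / n_tot
  p2 <- (pilot$a + pilot$c) / n_tot
  p <- pilot$a / n_tot
  psi <- p1 + p2 - 2 * p
  pbar <- psi / 2
  d <- p1 - p2
  if (d == 0) stop_validation("p1 = p2: no difference to power for")
  if (psi <= d^2) stop_validation("discordant mass <= d^2: formula domain error")
  z_alpha <- stats::qnorm(1 - alpha / 2)
  z_beta <- stats::qnorm(power)
  n_raw <- (z_alpha * sqrt(psi) + z_beta * sqrt(psi - d^2))^2 / d^2
  structure(list(n = as.integer(ceiling(n_raw)), n_raw = n_raw,
                 p1 = p1, p2 = p2, p = p, pbar = pbar, d = d, psi = psi,
                 z_alpha = z_alpha, z_beta = z_beta,
                 alpha = alpha, power = power, pilot = pilot),
            class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  cat("Paired diagnostic sample size\n")
  cat(sprintf("  p1 = %.4f, p2 = %.4f, p = %.4f, pbar = %.4f\n",
              x$p1, x$p2, x$p, x$pbar))
  cat(sprintf("  d = p1 - p2 = %.4f, psi = p1 + p2 - 2p = %.4f\n", x$d, x$psi))
  cat(sprintf("  alpha = %g (two-sided, z = %.4f), power = %g (z = %.4f)\n",
              x$alpha, x$z_alpha, x$power, x$z_beta))
  cat(sprintf("  n = %d (raw %.2f)\n", x$n, x$n_raw))
  invisible(x)
}
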