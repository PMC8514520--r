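## Coupling statistics and small helpers: partial correlation, 2x2
## chi-square, normal tail p-values.

#' One-sided upper normal tail probability
#'
#' `p = 1 - Phi(z)`.  Under this convention Z = 1.96 corresponds to
#' p = 0.025 and Z > 3.3 to p < 0.01.
#'
#' @param z finite numeric Z-score(s).
#' @return upper-tail probability.
#' @export
normal_upper_p <- function(z) stats::pnorm(z, lower.tail = FALSE)

#' Partial correlation via residual regressions
#'
#' Regresses `x` on `z` and `y` on `z` separately and reports the Pearson
#' correlation of the two residual vectors, the estimator behind a
#' residual plot of the partial correlation of x and y conditional on z.
#' The result equals the closed form
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' The two-sided p-value comes from `t = r sqrt((n - 3) / (1 - r^2))`
#' with n - 3 degrees of freedom.
#'
#' Abundance inputs are transform-agnostic here; the pipeline log10
#' transforms ppm with a 0.001 pseudocount before calling this.
#'
#' @param x,y,z numeric vectors of equal length n >= 4 with finite values.
#' @return an object of class `PartialCorrResult`: list with `r`, `p`,
#'   `n`, `residuals_x`, `residuals_y`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("x, y, z must have equal length")
  if (n < 4) stopf("partial correlation needs n >= 4")
  if (!all(is.finite(x), is.finite(y), is.finite(z)))
    stopf("non-finite values in input")
  if (stats::var(x) == 0 || stats::var(y) == 0 || stats::var(z) == 0)
    stopf("degenerate input: zero variance")
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  r <- stats::cor(rx, ry)
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 3, lower.tail = FALSE)
  structure(list(r = r, p = p, n = n, residuals_x = rx, residuals_y = ry),
            class = "PartialCorrResult")
}

#' @export
print.PartialCorrResult <- function(x, ...) {
  cat(sprintf("PartialCorrResult: r = %.4f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' 2x2 chi-square test
#'
#' Pearson chi-square on the table `[[a, b], [c, d]]` with 1 degree of
#' freedom and, by default, the Yates continuity correction (matching the
#' default of standard statistical environments for 2x2 tables).
#'
#' @param a,b,c,d nonnegative integer cell counts; all row and column
#'   marginals must be positive.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return an object of class `Chi2Result`: list with `chi2`, `df` (1),
#'   `p`, `yates`.
#' @export
chi2_2x2 <- function(a, b, c, d, yates = TRUE) {
  o <- c(a, b, c, d)
  if (any(o < 0) || any(o != round(o))) stopf("cell counts must be nonnegative integers")
  n <- sum(o)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) stopf("zero marginal in 2x2 table")
  e <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  dev <- abs(o - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / e)
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 yates = yates),
            class = "Chi2Result")
}

#' @export
print.Chi2Result <- function(x, ...) {
  cat(sprintf("Chi2Result: chi2 = %.4f (df = 1%s), p = %.3g\n",
              x$chi2, if (x$yates) ", Yates-corrected" else "", x$p))
  invisible(x)
}
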