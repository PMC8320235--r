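#' Parameter estimate for pairwise comparison
#'
#' @param value Fitted parameter value, nm.
#' @param ci95 95% confidence half-width of the fit, nm.
#' @param n Number of pooled cross-sections behind the fit.
#' @return List of class `paramEstimate`.
#' @export
paramEstimate <- function(value, ci95, n) {
  stopifnot(is.finite(value), ci95 >= 0)
  if (n < 2) stop("n must be >= 2")
  structure(list(value = value, ci95 = ci95, n = n),
            class = "paramEstimate")
}

#' Two-sided F-test comparison of two fitted shell parameters
#'
#' Compares two fitted parameters (e.g. shell radii of two labeling
#' conditions) by an F-test with numerator df 1 and denominator df
#' 0.5 (n1 + n2 - 2). Standard deviations are reconstructed from the
#' 95% confidence half-widths of the fits; under the default
#' reconstruction (`"ci-of-mean"`: sd = sqrt(n) ci95 / 1.96, treating
#' the fit CI as a standard error of the pooled estimate) the statistic
#' equals the square of the corresponding two-sample Welch-style t
#' statistic. The reconstruction is method-sensitive; an alternative
#' (`"ci-as-sd"`: sd = ci95 / 1.96) is selectable.
#'
#' @param a,b [paramEstimate()] objects.
#' @param reconstruction How to reconstruct per-section standard
#'   deviations from fit confidence intervals.
#' @return List with `F`, `df1`, `df2`, `p`, `reconstruction` and a
#'   `methodSensitive` flag.
#' @export
compareParams <- function(a, b,
                          reconstruction = c("ci-of-mean", "ci-as-sd")) {
  stopifnot(inherits(a, "paramEstimate"), inherits(b, "paramEstimate"))
  reconstruction <- match.arg(reconstruction)
  sdOf <- function(x) switch(reconstruction,
    "ci-of-mean" = sqrt(x$n) * x$ci95 / 1.96,
    "ci-as-sd" = x$ci95 / 1.96)
  s1 <- sdOf(a); s2 <- sdOf(b)
  se2 <- s1^2 / a$n + s2^2 / b$n
  tstat <- if (se2 == 0) 0 else (a$value - b$value) / sqrt(se2)
  Fstat <- tstat^2
  df2 <- 0.5 * (a$n + b$n - 2)
  p <- stats::pf(Fstat, df1 = 1, df2 = df2, lower.tail = FALSE)
  list(F = Fstat, df1 = 1, df2 = df2, p = p,
       reconstruction = reconstruction, methodSensitive = TRUE)
}
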