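# Power for the general linear model F test of one (or more) model terms,
# parameterised by Cohen's f2 effect size. Used to assess replication
# designs for associations discovered in the scan.

#' Power of the general linear model F test
#'
#' For numerator df `u`, denominator df `v`, effect size `f2` and level
#' `alpha`, the power is `P(F' > F_crit)` where `F_crit` is the upper-alpha
#' quantile of the central F(u, v) distribution and `F'` is noncentral
#' F(u, v) with noncentrality `lambda = f2 * (u + v + 1)` (the convention of
#' the classical f2 power calculation; `lambda = f2 * n` is available via
#' `lambda_convention = "n"`, where `n` must then be supplied).
#'
#' @param u numerator degrees of freedom (number of tested terms).
#' @param v denominator (error) degrees of freedom.
#' @param f2 Cohen's f2 = R2 / (1 - R2), >= 0.
#' @param alpha significance level in (0, 1).
#' @param lambda_convention `"u+v+1"` (default) or `"n"`.
#' @param n total sample size, required for `lambda_convention = "n"`.
#' @return power in (0, 1); exactly `alpha` when `f2 = 0`.
#' @export
power_f2 <- function(u, v, f2, alpha = 0.05,
                     lambda_convention = c("u+v+1", "n"), n = NULL) {
  if (u < 1 || v < 1) stop("u and v must be >= 1")
  if (f2 < 0) stop("f2 must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  lambda_convention <- match.arg(lambda_convention)
  lambda <- if (lambda_convention == "n") {
    if (is.null(n)) stop("n is required for lambda_convention = 'n'")
    f2 * n
  } else f2 * (u + v + 1)
  if (lambda == 0) return(alpha)  # null case: rejection rate is the level
  fcrit <- qf(alpha, u, v, lower.tail = FALSE)
  pf(fcrit, u, v, ncp = lambda, lower.tail = FALSE)
}

#' Power from a partial R-squared
#'
#' Bridges scan output to [power_f2()] via the standard conversion
#' `f2 = r2 / (1 - r2)`, with `u = 1` (a single genotype term) and
#' `v = n - n_model_terms - 1` error df.
#'
#' @param partial_r2 partial R-squared of the tested term, in `[0, 1)`.
#' @param n replication sample size.
#' @param n_model_terms number of model terms excluding the intercept
#'   (the discovery model has 6: sex, age, weight, genotype, PC1, PC2).
#' @param alpha significance level.
#' @return power in (0, 1).
#' @export
power_from_r2 <- function(partial_r2, n, n_model_terms = 6, alpha = 0.05) {
  if (any(partial_r2 < 0 | partial_r2 >= 1))
    stop("partial_r2 must lie in [0, 1)")
  if (any(n <= n_model_terms + 1))
    stop("n must exceed n_model_terms + 1")
  f2 <- partial_r2 / (1 - partial_r2)
  mapply(function(f, vv) power_f2(1, vv, f, alpha),
         f2, n - n_model_terms - 1)
}
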