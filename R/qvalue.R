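# Storey q-values with the smoother pi0 estimate. This is the FDR control
# used by both the association scan and the enrichment tests.

#' Storey q-values
#'
#' Estimates the null proportion pi0 with the smoother method — the natural
#' cubic smoothing spline of `pi0(lambda) = mean(p > lambda) / (1 - lambda)`
#' over the lambda grid, evaluated at the largest lambda, clamped to
#' (0, 1] — and computes
#' `q_i = min over { j : p_(j) >= p_i } of pi0 * m * p_(j) / rank(j)`.
#' With `pi0 = 1` this reduces exactly to the Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param lambda_grid grid for the pi0 smoother; lambdas at or above the
#'   largest p-value are dropped (the tail estimate would be 0/0-unstable).
#' @param pi0 optional fixed null proportion overriding the estimate
#'   (e.g. `pi0 = 1` for plain BH).
#' @return list with `q_values` (aligned to the input) and `pi0`.
#' @export
storey_qvalues <- function(p_values,
                           lambda_grid = seq(0.05, 0.90, by = 0.05),
                           pi0 = NULL) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 2) {
      pi0 <- 1
    } else {
      lam <- lambda_grid[lambda_grid < max(p)]
      if (length(lam) < 4) {
        pi0 <- 1
      } else {
        pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
        sp <- smooth.spline(lam, pi0_lam, df = 3)
        pi0 <- predict(sp, x = max(lam))$y
      }
    }
  }
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / (m:1)
  q <- pmin(cummin(q), 1)
  list(q_values = q[ro], pi0 = pi0)
}
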