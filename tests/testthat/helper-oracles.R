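# Independent oracles used to cross-check the package's statistics. Each is
# coded from the definition, by a different route than the implementation.

# Two-sided Fisher exact p by complete hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose probability
# does not exceed the observed table's.
fisher_enum_p <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  pr <- exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings,
# with U computed by direct pair counting (x_i > y_j plus half-ties).
mw_enum_p <- function(x, y) {
  pool <- c(x, y); n1 <- length(x); n <- length(pool)
  u_pairs <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_pairs(x, y) - mu)
  sets <- combn(n, n1)
  us <- apply(sets, 2, function(i) u_pairs(pool[i], pool[-i]))
  mean(abs(us - mu) >= obs - 1e-9)
}

# Gaussian-likelihood LRT for the genotype term via explicit log-likelihoods
# at the MLE (sigma2_hat = RSS/n), using lm() fits.
gauss_lrt_oracle <- function(y, covariates, surrogate, g) {
  d <- data.frame(y = y, sex = covariates$sex, age = covariates$age,
                  weight = covariates$weight_category,
                  pc1 = surrogate$pc1, pc2 = surrogate$pc2, g = g)
  d <- d[stats::complete.cases(d), ]
  f1 <- stats::lm(y ~ sex + age + weight + pc1 + pc2 + g, data = d)
  f0 <- stats::lm(y ~ sex + age + weight + pc1 + pc2, data = d)
  ll <- function(f) {
    n <- length(stats::residuals(f))
    s2 <- sum(stats::residuals(f)^2) / n
    -n / 2 * (log(2 * pi * s2) + 1)
  }
  stat <- 2 * (ll(f1) - ll(f0))
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Vectorised Monte-Carlo power oracle for the 1-df F test in a Gaussian
# regression: simulate y = b*x + e with b chosen so the noncentrality is
# f2 * (u + v + 1), and count rejections of the slope's F test.
mc_power_oracle <- function(f2, v, alpha = 0.05, nrep = 1e5, seed = 1) {
  set.seed(seed)
  n <- v + 2
  x <- scale(seq_len(n))[, 1]
  lambda <- f2 * (1 + v + 1)
  b <- sqrt(lambda / sum(x^2))
  fcrit <- stats::qf(1 - alpha, 1, v)
  hits <- 0; chunk <- 10000
  for (i in seq_len(ceiling(nrep / chunk))) {
    k <- min(chunk, nrep - (i - 1) * chunk)
    Y <- matrix(stats::rnorm(n * k), n) + b * x
    bh <- crossprod(x, Y)[1, ] / sum(x^2)
    rss1 <- colSums(Y^2) - n * colMeans(Y)^2 - bh^2 * sum(x^2)
    Fst <- bh^2 * sum(x^2) / (rss1 / (n - 2))
    hits <- hits + sum(Fst > fcrit)
  }
  hits / nrep
}
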