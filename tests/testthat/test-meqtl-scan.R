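# Cis pairing, genotype collapsing, the adjusted LRT model, and the scan.

test_that("cis pairing is inclusive at the window boundary", {
  snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 1000000L)
  probes <- data.frame(probe_id = c("at_snp", "in_", "edge", "out"),
                       chrom = "chr1",
                       pos = c(1000000L, 1200000L, 1500000L, 1500001L))
  p <- pair_cis(snps, probes, window = 500000)
  expect_setequal(p$probe_id, c("at_snp", "in_", "edge"))
  expect_equal(p$distance[p$probe_id == "at_snp"], 0)
  expect_equal(p$distance[p$probe_id == "edge"], 500000)
})

test_that("cis pairing matches brute-force enumeration on a toy manifest", {
  cfg <- tiny_config()
  p <- pair_cis(cfg$snp_specs, cfg$probe_specs, window = 500000)
  # brute force over all SNP x probe combinations
  ref <- expand.grid(s = seq_len(2), q = seq_len(5))
  ref$d <- abs(cfg$snp_specs$pos[ref$s] - cfg$probe_specs$pos[ref$q])
  ref <- ref[ref$d <= 500000, ]
  got <- paste(p$snp_id, p$probe_id)
  want <- paste(cfg$snp_specs$snp_id[ref$s], cfg$probe_specs$probe_id[ref$q])
  expect_setequal(got, want)
  expect_equal(sort(p$distance), sort(ref$d))
  # per-SNP counts reported
  expect_equal(sum(attr(p, "per_snp")), nrow(p))
})

test_that("rare homozygote classes collapse below a count of 10", {
  mk <- function(n0, n1, n2) c(rep(0, n0), rep(1, n1), rep(2, n2))
  e <- encode_and_collapse(mk(200, 120, 9))
  expect_true(e$collapsed)
  expect_setequal(unique(e$dosage), c(0, 1))
  expect_equal(sum(e$dosage == 1), 129)

  e2 <- encode_and_collapse(mk(5, 150, 200))  # rule applies to either side
  expect_true(e2$collapsed)
  expect_setequal(unique(e2$dosage), c(0, 1))
  expect_equal(sum(e2$dosage == 0), 155)

  e3 <- encode_and_collapse(mk(100, 100, 10))  # 10 is not "less than 10"
  expect_false(e3$collapsed)
  expect_setequal(unique(e3$dosage), c(0, 1, 2))

  # missing genotypes are masked, monomorphic SNPs untestable
  e4 <- encode_and_collapse(c(1, 1, NA, 1))
  expect_equal(e4$mask, c(TRUE, TRUE, FALSE, TRUE))
  expect_false(e4$testable)
  expect_error(encode_and_collapse(c(0, 3)), "must be 0, 1, 2")
})

test_that("degenerate fits hit their analytic limits", {
  d <- random_design(80, seed = 31)
  # covariate-only noise-free signal: nothing left for the genotype
  y <- 2 + 0.5 * d$cov$sex - 0.1 * d$cov$age
  r <- fit_association(y, d$cov, d$sur, d$g)
  expect_equal(r$p_value, 1)
  expect_equal(r$partial_r2, 0)

  # y an exact function of the genotype: partial R2 = 1
  y2 <- 1 + 0.7 * d$g
  r2 <- fit_association(y2, d$cov, d$sur, d$g)
  expect_equal(r2$partial_r2, 1)
  expect_lt(r2$p_value, 1e-100)

  # constant dosage is untestable, not an error
  r3 <- fit_association(rnorm(80), d$cov, d$sur, rep(1, 80))
  expect_false(r3$testable)

  # collinear covariates are named
  d2 <- d; d2$sur$pc2 <- d2$sur$pc1
  expect_error(fit_association(rnorm(80), d2$cov, d2$sur, d2$g),
               "pc2")
})

test_that("the LRT equals the Gaussian-likelihood oracle and tracks the partial F test", {
  skip_if_not_installed("lmtest")
  for (seed in 1:25) {
    d <- random_design(sample(60:250, 1), seed = 300 + seed)
    y <- rnorm(length(d$g)) + 0.15 * d$g + 0.3 * d$sur$pc1
    r <- fit_association(y, d$cov, d$sur, d$g)
    o <- gauss_lrt_oracle(y, d$cov, d$sur, d$g)
    expect_equal(r$lrt_stat, o$stat, tolerance = 1e-8)
    expect_equal(r$p_value, o$p, tolerance = 1e-10)
    # cross-check against lmtest, the conventional implementation
    df_ <- data.frame(y = y, d$cov, pc1 = d$sur$pc1, pc2 = d$sur$pc2,
                      g = d$g)
    lt <- lmtest::lrtest(
      lm(y ~ sex + age + weight_category + pc1 + pc2 + g, df_),
      lm(y ~ sex + age + weight_category + pc1 + pc2, df_))
    expect_equal(r$lrt_stat, lt$Chisq[2], tolerance = 1e-8)
  }
  # asymptotic equivalence with the partial F test at n = 200
  d <- random_design(200, seed = 77)
  y <- rnorm(200) + 0.2 * d$g
  r <- fit_association(y, d$cov, d$sur, d$g)
  df_ <- data.frame(y = y, d$cov, pc1 = d$sur$pc1, pc2 = d$sur$pc2, g = d$g)
  pf_p <- anova(lm(y ~ sex + age + weight_category + pc1 + pc2, df_),
                lm(y ~ sex + age + weight_category + pc1 + pc2 + g, df_))$
    `Pr(>F)`[2]
  expect_lt(abs(r$p_value - pf_p) / pf_p, 0.10)
})

test_that("partial R2 is invariant to affine rescaling of covariates", {
  d <- random_design(150, seed = 41)
  y <- rnorm(150) + 0.3 * d$g + 0.2 * d$cov$sex
  r1 <- fit_association(y, d$cov, d$sur, d$g)
  d2 <- d
  d2$cov$age <- (d2$cov$age - 20) / 10
  d2$sur$pc1 <- 5 * d2$sur$pc1 + 2
  r2 <- fit_association(y, d2$cov, d2$sur, d2$g)
  expect_equal(r1$partial_r2, r2$partial_r2, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("a single-pair scan reduces to q = p", {
  cfg <- sim_pairs_config(1, n_samples = 120, seed = 51)
  sc <- scan_simulated_pairs(cfg)
  expect_equal(sc$results$q_value, sc$results$p_value)
  expect_equal(sc$pi0, 1)
})

test_that("planted effects are detected and nulls controlled in a mixed scan", {
  cfg <- sim_pairs_config(50, n_true = 10, delta = 1.0, seed = 52)
  sc <- scan_simulated_pairs(cfg)
  true_key <- paste(cfg$effect_specs$snp_id, cfg$effect_specs$probe_id)
  sig_key <- paste(sc$significant$snp_id, sc$significant$probe_id)
  expect_true(all(true_key %in% sig_key))
  expect_lte(sum(!sig_key %in% true_key), 2)
  # q monotone nondecreasing in p within the scan
  o <- order(sc$results$p_value)
  expect_true(all(diff(sc$results$q_value[o]) >= -1e-12))
})

test_that("sub-group concordance counts sign agreement and raw significance", {
  cfg <- sim_pairs_config(12, n_true = 12, delta = 1.5, n_samples = 300,
                          seed = 53)
  ds <- simulate_dataset(cfg)
  m <- beta_to_m(ds$beta)
  surr <- cell_surrogate(m, cfg$reference_probe_ids)
  pairs <- pair_cis(cfg$snp_specs, cfg$probe_specs)
  pairs <- pairs[!grepl("^cgref", pairs$probe_id), ]
  half <- seq_len(150)
  sub_scan <- function(idx) {
    s <- list(pc1 = surr$pc1[idx], pc2 = surr$pc2[idx])
    run_scan(m[idx, ], ds$covariates[idx, ], s, ds$genotypes[idx, ], pairs)
  }
  a <- sub_scan(half); b <- sub_scan(-half)
  conc <- subgroup_concordance(a$results, b$results, pairs)
  expect_equal(conc$sign_agreement, 1)  # strong effects: full agreement
  expect_equal(conc$n_pairs, 12)
  expect_gt(conc$n_raw_sig_a, 10)

  # flipping one table's coefficients destroys agreement
  b_flip <- b$results; b_flip$coef_genotype <- -b_flip$coef_genotype
  expect_equal(subgroup_concordance(a$results, b_flip, pairs)$sign_agreement,
               0)
  # missing pairs are reported
  expect_error(
    subgroup_concordance(a$results[-1, ], b$results, pairs), "missing")
})
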