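# The cis association scan: SNP-CpG pairing within a window, rare-genotype
# collapsing, the covariate-adjusted linear model with a likelihood ratio
# test on the genotype term, and Storey q-value FDR control.

#' Enumerate cis SNP-CpG pairs
#'
#' All (SNP, probe) pairs on the same chromosome with
#' `|snp_pos - probe_pos| <= window`. The boundary is inclusive: a probe
#' exactly `window` bp away is tested.
#'
#' @param snp_manifest data.frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param probe_manifest data.frame with `probe_id`, `chrom`, `pos`.
#' @param window cis window in bp.
#' @return data.frame with `snp_id`, `probe_id`, `distance`, plus an
#'   attribute `per_snp` giving the pair count per SNP.
#' @export
pair_cis <- function(snp_manifest, probe_manifest, window = 500000) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snp_manifest)),
            all(c("probe_id", "chrom", "pos") %in% names(probe_manifest)))
  out <- list()
  for (chrom in unique(snp_manifest$chrom)) {
    s <- snp_manifest[snp_manifest$chrom == chrom, ]
    p <- probe_manifest[probe_manifest$chrom == chrom, ]
    if (nrow(p) == 0) next
    for (i in seq_len(nrow(s))) {
      d <- abs(p$pos - s$pos[i])
      keep <- d <= window
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          snp_id = s$snp_id[i], probe_id = p$probe_id[keep],
          distance = d[keep], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(), probe_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  attr(pairs, "per_snp") <- table(factor(pairs$snp_id,
                                         levels = snp_manifest$snp_id))
  pairs
}

#' Encode a dosage vector and collapse rare homozygote classes
#'
#' Dosages count risk alleles (non-risk homozygote = 0, heterozygote = 1,
#' risk homozygote = 2). Samples with missing genotype are masked out. A
#' homozygote class observed in fewer than `min_homozygote_count` samples
#' (but at least one) is merged with the heterozygote class and the
#' variable recoded to two levels 0/1. A SNP monomorphic after masking and
#' collapsing is flagged untestable.
#'
#' @param dosages numeric vector with values in `{0, 1, 2, NA}`.
#' @param min_homozygote_count minimum homozygote class size kept separate.
#' @return list with `dosage` (recoded analysis vector, NA where masked),
#'   `mask` (logical complete-case indicator), `collapsed` (flag),
#'   `testable` (flag).
#' @export
encode_and_collapse <- function(dosages, min_homozygote_count = 10) {
  d <- as.numeric(dosages)
  if (any(!(d %in% c(0, 1, 2)) & !is.na(d)))
    stop("dosages must be 0, 1, 2 or NA")
  mask <- !is.na(d)
  counts <- c(`0` = sum(d == 0, na.rm = TRUE),
              `1` = sum(d == 1, na.rm = TRUE),
              `2` = sum(d == 2, na.rm = TRUE))
  collapsed <- FALSE
  if (counts["2"] > 0 && counts["2"] < min_homozygote_count) {
    d[d == 2] <- 1
    collapsed <- TRUE
  }
  if (counts["0"] > 0 && counts["0"] < min_homozygote_count) {
    d[d == 0] <- 1
    collapsed <- TRUE
  }
  lev <- sort(unique(d[mask]))
  testable <- length(lev) >= 2
  if (collapsed && testable) d <- match(d, lev) - 1
  list(dosage = d, mask = mask, collapsed = collapsed, testable = testable)
}

#' Fit the covariate-adjusted association model for one SNP-CpG pair
#'
#' Fits the full model
#' `M = a + bS*sex + bA*age + bW*weight + bG*G + bPC1*PC1 + bPC2*PC2 + eps`
#' and the reduced model without the genotype term, both by least squares
#' on complete cases. The genotype term is tested with the Gaussian
#' likelihood ratio statistic `n * ln(RSS_reduced / RSS_full)`, referred to
#' a chi-square with 1 df. The effect size is the partial R-squared
#' `(RSS_reduced - RSS_full) / RSS_reduced`: the share of methylation
#' variance not already explained by the covariates that the SNP explains.
#' A plain marginal R-squared (M on dosage alone) is also reported.
#'
#' @param m_values per-sample M values for one probe.
#' @param covariates data.frame with `sex`, `age`, `weight_category`
#'   aligned to `m_values`.
#' @param surrogate a [cell_surrogate()] object (or list with `pc1`,
#'   `pc2`), aligned to `m_values`; NULL to omit the composition terms.
#' @param dosage encoded analysis dosage (see [encode_and_collapse()]),
#'   NA for masked samples.
#' @param collapsed logical carried through to the result.
#' @return one-row data.frame: `coef_genotype`, `se_genotype`,
#'   `coef_sex`, `coef_age`, `coef_weight`, `coef_pc1`, `coef_pc2`,
#'   `intercept`, `lrt_stat`, `p_value`, `partial_r2`, `marginal_r2`,
#'   `n_used`, `collapsed`, `testable`.
#' @export
fit_association <- function(m_values, covariates, surrogate, dosage,
                            collapsed = FALSE) {
  n_all <- length(m_values)
  if (nrow(covariates) != n_all || length(dosage) != n_all)
    stop("inputs are not sample-aligned")
  Xr <- cbind(intercept = 1, sex = covariates$sex, age = covariates$age,
              weight = covariates$weight_category)
  if (!is.null(surrogate)) {
    if (length(surrogate$pc1) != n_all)
      stop("surrogate is not sample-aligned")
    Xr <- cbind(Xr, pc1 = surrogate$pc1, pc2 = surrogate$pc2)
  }
  cc <- complete.cases(Xr) & !is.na(dosage) & !is.na(m_values)
  y <- m_values[cc]; g <- dosage[cc]; Xr <- Xr[cc, , drop = FALSE]
  n <- length(y)
  na_row <- data.frame(coef_genotype = NA_real_, se_genotype = NA_real_,
                       coef_sex = NA_real_, coef_age = NA_real_,
                       coef_weight = NA_real_, coef_pc1 = NA_real_,
                       coef_pc2 = NA_real_, intercept = NA_real_,
                       lrt_stat = NA_real_, p_value = NA_real_,
                       partial_r2 = NA_real_, marginal_r2 = NA_real_,
                       n_used = n, collapsed = collapsed, testable = FALSE)
  if (length(unique(g)) < 2) return(na_row)
  Xf <- cbind(Xr, genotype = g)
  if (n < ncol(Xf) + 2) return(na_row)
  qf_ <- qr(Xf)
  if (qf_$rank < ncol(Xf)) {
    keep <- qf_$pivot[seq_len(qf_$rank)]
    bad <- colnames(Xf)[setdiff(seq_len(ncol(Xf)), keep)]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit_full <- qr.coef(qf_, y)
  rss_full <- sum(qr.resid(qf_, y)^2)
  qr_ <- qr(Xr)
  rss_red <- sum(qr.resid(qr_, y)^2)

  # a reduced model that already fits exactly leaves nothing for G to explain
  tol0 <- .Machine$double.eps * max(1, sum(y^2))
  if (rss_red <= tol0) {
    lrt <- 0; pr2 <- 0
  } else {
    lrt <- n * log(rss_red / rss_full)  # Inf when the full fit is exact
    pr2 <- (rss_red - rss_full) / rss_red
  }
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  # OLS standard error of the genotype coefficient
  XtXinv <- chol2inv(chol(crossprod(Xf)))
  sigma2 <- rss_full / (n - ncol(Xf))
  se_g <- sqrt(sigma2 * XtXinv[ncol(Xf), ncol(Xf)])
  mr2 <- cor(y, g)^2

  data.frame(
    coef_genotype = unname(fit_full["genotype"]), se_genotype = se_g,
    coef_sex = unname(fit_full["sex"]), coef_age = unname(fit_full["age"]),
    coef_weight = unname(fit_full["weight"]),
    coef_pc1 = if ("pc1" %in% names(fit_full))
      unname(fit_full["pc1"]) else NA_real_,
    coef_pc2 = if ("pc2" %in% names(fit_full))
      unname(fit_full["pc2"]) else NA_real_,
    intercept = unname(fit_full["intercept"]),
    lrt_stat = lrt, p_value = max(p, .Machine$double.xmin),
    partial_r2 = min(max(pr2, 0), 1), marginal_r2 = mr2,
    n_used = n, collapsed = collapsed, testable = TRUE)
}

#' Run the cis-meQTL scan
#'
#' Fits [fit_association()] for every cis pair, pools all testable pairs
#' into one q-value family, and flags associations with `q < q_threshold`.
#'
#' @param m_values samples x probes M-value matrix (QC'd).
#' @param covariates covariate table aligned to the matrix rows.
#' @param surrogate [cell_surrogate()] aligned to the matrix rows, or NULL.
#' @param genotypes samples x SNPs dosage matrix (0/1/2/NA, risk-allele
#'   oriented).
#' @param pairs cis pair table from [pair_cis()].
#' @param q_threshold significance cutoff on the q-value.
#' @param min_homozygote_count rare-homozygote collapsing threshold.
#' @return list with `results` (one row per testable pair, q-values and
#'   `significant` flag included) and `significant` (the q < threshold
#'   subset), plus `pi0` and `n_untestable`.
#' @export
run_scan <- function(m_values, covariates, surrogate, genotypes, pairs,
                     q_threshold = 0.05, min_homozygote_count = 10) {
  if (nrow(pairs) == 0) stop("zero cis pairs supplied")
  pairs <- pairs[pairs$probe_id %in% colnames(m_values) &
                   pairs$snp_id %in% colnames(genotypes), , drop = FALSE]
  if (nrow(pairs) == 0) stop("zero testable pairs after matching inputs")

  enc <- lapply(unique(pairs$snp_id), function(s)
    encode_and_collapse(genotypes[, s], min_homozygote_count))
  names(enc) <- unique(pairs$snp_id)

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    e <- enc[[pairs$snp_id[i]]]
    if (!e$testable) {
      rows[[i]] <- NULL
      next
    }
    r <- fit_association(m_values[, pairs$probe_id[i]], covariates,
                         surrogate, e$dosage, collapsed = e$collapsed)
    rows[[i]] <- cbind(pairs[i, , drop = FALSE], r)
  }
  keep <- !vapply(rows, is.null, logical(1))
  res <- do.call(rbind, rows[keep])
  res <- res[res$testable, , drop = FALSE]
  if (nrow(res) == 0) stop("zero testable pairs")
  rownames(res) <- NULL

  qv <- storey_qvalues(res$p_value)
  res$q_value <- qv$q_values
  res$significant <- res$q_value < q_threshold
  ord <- c("snp_id", "probe_id", "distance", "n_used", "collapsed",
           "coef_genotype", "se_genotype", "lrt_stat", "p_value",
           "q_value", "partial_r2", "marginal_r2", "significant")
  res_out <- res[, c(ord, setdiff(names(res), ord))]
  list(results = res_out,
       significant = res_out[res_out$significant, , drop = FALSE],
       pi0 = qv$pi0,
       n_untestable = sum(!keep) + sum(!res$testable))
}

#' Sub-group concordance of association signs
#'
#' Compares two scans over the same pairs: counts pairs whose genotype
#' coefficients agree in sign, and pairs with raw `p < p_threshold` in
#' each sub-group. Used to check that pooled discovery results are not
#' driven by one sub-group.
#'
#' @param results_a,results_b result tables from [run_scan()].
#' @param pair_subset data.frame with `snp_id`, `probe_id` of the pairs to
#'   compare (e.g. the significant pairs of the pooled scan).
#' @param p_threshold raw significance cutoff within each sub-group.
#' @return list with `n_pairs`, `n_sign_agree`, `sign_agreement`
#'   (fraction), `n_raw_sig_a`, `n_raw_sig_b`.
#' @export
subgroup_concordance <- function(results_a, results_b, pair_subset,
                                 p_threshold = 0.05) {
  key <- function(d) paste(d$snp_id, d$probe_id, sep = "\r")
  ka <- key(results_a); kb <- key(results_b); ks <- key(pair_subset)
  ia <- match(ks, ka); ib <- match(ks, kb)
  missing <- ks[is.na(ia) | is.na(ib)]
  if (length(missing))
    stop("pairs missing from a result table: ",
         paste(gsub("\r", "/", missing), collapse = ", "))
  ca <- results_a$coef_genotype[ia]
  cb <- results_b$coef_genotype[ib]
  agree <- sign(ca) == sign(cb)
  list(n_pairs = length(ks),
       n_sign_agree = sum(agree),
       sign_agreement = mean(agree),
       n_raw_sig_a = sum(results_a$p_value[ia] < p_threshold),
       n_raw_sig_b = sum(results_b$p_value[ib] < p_threshold))
}
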