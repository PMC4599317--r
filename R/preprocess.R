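# Methylation matrix QC and transformation: beta <-> M, probe exclusion,
# variable-probe selection, PCA-based sample outlier exclusion, and the
# two-PC cell-composition surrogate.

#' Convert beta values to M values
#'
#' `M = log2(beta / (1 - beta))`, the logit2 of the methylated fraction.
#' Values exactly 0 or 1 are clamped to `[eps, 1 - eps]` first to avoid
#' infinities; values outside `[0, 1]` are a domain error.
#'
#' @param beta numeric vector or matrix of beta values in `[0, 1]`.
#' @param eps clamping bound for boundary values.
#' @return M values, same shape as the input.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  out
}

#' Convert M values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (2^M + 1)`.
#'
#' @param m numeric vector or matrix of M values.
#' @return beta values in (0, 1), same shape.
#' @export
m_to_beta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  dimnames(out) <- dimnames(m)
  out
}

#' Filter probes on quality and annotation flags
#'
#' Removes probes with any missing beta value, probes whose fraction of
#' samples with detection p-value below `p_threshold` is strictly less
#' than `min_fraction`, probes on the sex chromosomes, cross-reactive
#' probes, and probes containing common SNPs, as flagged in `flags`.
#'
#' @param beta samples x probes beta matrix.
#' @param detection_p matrix of detection p-values aligned to `beta`.
#' @param flags data.frame with `probe_id` and logical columns
#'   `is_sex_chromosome`, `is_cross_reactive`, `has_maf_gt1pct_snp`.
#' @param min_fraction minimum fraction of samples that must pass
#'   detection (retained iff fraction >= `min_fraction`).
#' @param p_threshold detection p-value cutoff defining "pass".
#' @return list with `beta` (filtered matrix) and `report`
#'   (per-reason exclusion counts and the excluded ids per reason).
#' @export
filter_probes <- function(beta, detection_p, flags,
                          min_fraction = 0.75, p_threshold = 0.01) {
  if (!identical(dim(beta), dim(detection_p)))
    stop("beta and detection_p dimensions differ")
  pid <- colnames(beta)
  if (is.null(pid)) stop("beta must have probe ids as column names")
  if (!identical(pid, colnames(detection_p)))
    stop("beta and detection_p probe ids differ")
  fl <- flags[match(pid, flags$probe_id), , drop = FALSE]
  if (anyNA(fl$probe_id)) stop("flags missing for some probes")

  missing_beta <- colSums(is.na(beta)) > 0
  pass_frac <- colMeans(detection_p < p_threshold, na.rm = FALSE)
  detection_fail <- pass_frac < min_fraction
  reasons <- cbind(
    missing_beta = missing_beta,
    detection_fail = detection_fail,
    sex_chromosome = as.logical(fl$is_sex_chromosome),
    cross_reactive = as.logical(fl$is_cross_reactive),
    snp_overlap = as.logical(fl$has_maf_gt1pct_snp))
  drop <- rowSums(reasons, na.rm = TRUE) > 0
  report <- list(
    n_input = length(pid),
    n_excluded = sum(drop),
    n_retained = sum(!drop),
    counts = colSums(reasons, na.rm = TRUE),
    excluded = lapply(as.data.frame(reasons), function(r) pid[which(r)]))
  list(beta = beta[, !drop, drop = FALSE], report = report)
}

#' 95 % reference range of a beta vector
#'
#' The difference between the 97.5th and 2.5th percentiles, computed with
#' linear interpolation between order statistics (quantile type 7). Used to
#' select the most variable probes.
#'
#' @param values numeric vector of per-sample beta values for one probe.
#' @return nonnegative scalar range.
#' @export
reference_range_95 <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("reference_range_95 needs >= 2 finite values")
  q <- quantile(v, c(0.025, 0.975), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Select variable probes by 95 % reference range
#'
#' @param beta samples x probes beta matrix.
#' @param min_range minimum 95 % reference range for retention
#'   (retained iff range >= `min_range`).
#' @return list with `beta` (filtered) and `ranges` (named per-probe).
#' @export
select_variable_probes <- function(beta, min_range = 0.20) {
  r <- apply(beta, 2, reference_range_95)
  keep <- r >= min_range
  list(beta = beta[, keep, drop = FALSE], ranges = r)
}

#' Principal component analysis of a sample x feature matrix
#'
#' Column-centred PCA (no scaling). Variance fractions are the squared
#' singular values over their total; the sign of each component is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param x samples x features numeric matrix.
#' @param n_components number of components to return; truncated with a
#'   warning if it exceeds the matrix rank.
#' @return list with `scores` (samples x k), `loadings` (features x k),
#'   `variance_fraction` (length k, fractions of the total variance).
#' @export
pca <- function(x, n_components = min(dim(x))) {
  x <- as.matrix(x)
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (n_components > rank_max) {
    warning(sprintf("n_components truncated from %d to rank %d",
                    n_components, rank_max))
    n_components <- rank_max
  }
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- pr$x[, seq_len(k), drop = FALSE]
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, loadings = load,
       variance_fraction = vf[seq_len(k)],
       variance_fraction_all = vf)
}

#' Exclude sample outliers on the leading principal components
#'
#' A sample is excluded if its score on any of the first `n_pcs`
#' components lies more than `z_threshold` standard deviations from that
#' component's mean.
#'
#' @param scores samples x components score matrix (from [pca()]).
#' @param n_pcs number of leading components examined.
#' @param z_threshold per-component z-score cutoff.
#' @return list with `retained` (sample ids), `excluded` (ids), and
#'   `report` (data.frame naming the offending component and z per
#'   excluded sample).
#' @export
exclude_outlier_samples <- function(scores, n_pcs = 8, z_threshold = 3) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3) stop("need >= 3 samples to define outliers")
  if (ncol(scores) < n_pcs)
    stop(sprintf("scores cover %d components; %d requested",
                 ncol(scores), n_pcs))
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(scores)))
  z <- scale(scores[, seq_len(n_pcs), drop = FALSE])
  # a constant component has SD 0; no sample can be an outlier on it
  z[, attr(z, "scaled:scale") == 0] <- 0
  bad <- abs(z) > z_threshold
  out_idx <- which(rowSums(bad) > 0)
  report <- do.call(rbind, lapply(out_idx, function(i) {
    j <- which(bad[i, ])[1]
    data.frame(sample_id = ids[i], pc = j, z = z[i, j],
               stringsAsFactors = FALSE)
  }))
  if (is.null(report))
    report <- data.frame(sample_id = character(), pc = integer(),
                         z = numeric(), stringsAsFactors = FALSE)
  list(retained = ids[setdiff(seq_len(nrow(scores)), out_idx)],
       excluded = ids[out_idx], report = report)
}

#' Cell-type composition surrogate from a reference CpG panel
#'
#' Restricts the M-value matrix to a panel of cell-type discriminating
#' reference probes and takes the first two principal components of that
#' panel as a surrogate for cell-type proportions (entered as PC1 and PC2
#' covariates in the association model).
#'
#' @param m_values samples x probes M-value matrix.
#' @param reference_probe_ids the reference panel; at least 2 must be
#'   present in the matrix (absent ones are reported with a warning).
#' @return list of class `cell_surrogate` with `pc1`, `pc2` (named
#'   per-sample scores), `loadings`, and `variance_explained` (fractions
#'   for PC1 and PC2 of the panel's total variance).
#' @export
cell_surrogate <- function(m_values, reference_probe_ids) {
  present <- intersect(reference_probe_ids, colnames(m_values))
  absent <- setdiff(reference_probe_ids, colnames(m_values))
  if (length(absent))
    warning("reference probes absent from matrix: ",
            paste(absent, collapse = ", "))
  if (length(present) < 2)
    stop("fewer than 2 reference probes present after QC")
  p <- pca(m_values[, present, drop = FALSE], n_components = 2)
  structure(list(
    pc1 = p$scores[, 1], pc2 = p$scores[, 2],
    loadings = p$loadings,
    variance_explained = p$variance_fraction[1:2],
    reference_probe_ids = present), class = "cell_surrogate")
}

#' Full methylation preprocessing stage
#'
#' Applies [filter_probes()], converts to M values, runs the PCA sample
#' outlier exclusion on the most variable probes, and builds the cell
#' surrogate, returning everything the association scan needs.
#'
#' @param beta samples x probes beta matrix.
#' @param detection_p aligned detection p-value matrix.
#' @param flags probe flag data.frame (see [filter_probes()]).
#' @param reference_probe_ids cell-type reference panel.
#' @param min_fraction,p_threshold detection filter parameters.
#' @param min_range 95 % reference-range threshold for the variable-probe
#'   set used by the outlier PCA.
#' @param n_pcs,z_threshold sample outlier rule (see
#'   [exclude_outlier_samples()]).
#' @return list with `m_values` (QC'd samples x probes), `surrogate`,
#'   `probe_report`, `sample_report`, `retained_samples`.
#' @export
preprocess_methylation <- function(beta, detection_p, flags,
                                   reference_probe_ids,
                                   min_fraction = 0.75, p_threshold = 0.01,
                                   min_range = 0.20,
                                   n_pcs = 8, z_threshold = 3) {
  fp <- filter_probes(beta, detection_p, flags, min_fraction, p_threshold)
  m <- beta_to_m(fp$beta)
  sel <- select_variable_probes(fp$beta, min_range)
  n_pcs_eff <- min(n_pcs, nrow(m) - 1L, ncol(sel$beta))
  if (ncol(sel$beta) >= 2) {
    p_out <- pca(beta_to_m(sel$beta), n_components = n_pcs_eff)
    ex <- exclude_outlier_samples(p_out$scores, n_pcs = n_pcs_eff,
                                  z_threshold = z_threshold)
  } else {
    ex <- list(retained = rownames(m), excluded = character(),
               report = data.frame())
  }
  m <- m[ex$retained, , drop = FALSE]
  surr <- cell_surrogate(m, reference_probe_ids)
  list(m_values = m, surrogate = surr, probe_report = fp$report,
       sample_report = ex$report, retained_samples = ex$retained,
       excluded_samples = ex$excluded,
       variable_probe_ranges = sel$ranges)
}
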