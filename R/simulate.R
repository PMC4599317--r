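# Synthetic cohort generator: covariates, genotypes, cell compositions,
# methylation with planted cis effects, and annotation fixtures with ground
# truth. Every downstream stage of the pipeline is testable against these.

#' The seven collapsed chromatin-state categories
#'
#' Chromatin-state segmentations are consumed with their state labels mapped
#' onto seven broad categories commonly used when summarising an 18-state
#' segmentation model.
#'
#' @export
STATE_CATEGORIES <- c("enhancer", "tss", "transcription", "quiescent",
                      "heterochromatin", "polycomb", "znf_repeats")

#' Build a simulation configuration
#'
#' Collects every knob of the synthetic cohort in one validated object:
#' sample-level covariate distributions, SNP and probe manifests, planted
#' additive genotype effects on the M scale, per-probe covariate
#' coefficients, the cell-mixture structure, and noise.
#'
#' The generative model per probe k and sample i is
#' \deqn{M_{ik} = base_k + \sum_c w_{ic}\,o_{kc} + b_{kS}S_i + b_{kA}A_i +
#'   b_{kW}W_i + \delta_{k}\,G_i + \epsilon_{ik}}
#' where `w` are Dirichlet cell-composition weights, `o` per-probe
#' per-cell-type logit offsets, and `eps ~ N(0, noise_sd^2)`. Beta values
#' are `2^M / (2^M + 1)`.
#'
#' @param n_samples number of individuals (>= 2).
#' @param snp_specs data.frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based bp), `risk_allele`, `maf` in (0, 0.5].
#' @param probe_specs data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based bp), `base_level` (logit-scale methylation).
#' @param effect_specs data.frame with columns `snp_id`, `probe_id`,
#'   `delta` (M-units per risk allele); ids must exist in the manifests.
#' @param covariate_effects data.frame with columns `probe_id`, `sex`,
#'   `age`, `weight` (per-probe M-scale coefficients), or NULL for zero.
#' @param celltype_offsets numeric matrix, probes x cell types, of logit
#'   shifts mixed linearly by the composition weights; NULL for none.
#' @param reference_probe_ids probes designated cell-type discriminating
#'   (the surrogate panel); must be a subset of the probe manifest.
#' @param noise_sd residual SD on the M scale (> 0).
#' @param dirichlet_alpha per-cell-type Dirichlet concentrations; names are
#'   the cell-type labels.
#' @param sex_prob probability of sex = 1 (female).
#' @param age_range uniform age range in years.
#' @param weight_probs probabilities of weight category 0/1/2
#'   (normal weight / overweight / obese).
#' @param missing_rate per-entry genotype missingness probability.
#' @param detection_fail_rate probability that a (sample, probe) detection
#'   p-value is drawn from the failure distribution.
#' @param chrom_lengths named integer vector of chromosome lengths used by
#'   the annotation generator.
#' @param seed integer seed; all generators derive their streams from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples,
                       snp_specs,
                       probe_specs,
                       effect_specs = NULL,
                       covariate_effects = NULL,
                       celltype_offsets = NULL,
                       reference_probe_ids = character(),
                       noise_sd = 0.5,
                       dirichlet_alpha = c(gran = 10, cd4t = 4, cd8t = 2.5,
                                           bcell = 1.5, nk = 1.5, mono = 1.5),
                       sex_prob = 0.4,
                       age_range = c(14, 34),
                       weight_probs = c(0.76, 0.20, 0.04),
                       missing_rate = 0,
                       detection_fail_rate = 0.002,
                       chrom_lengths = c(chrS = 2e6),
                       seed = 1L) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L)
  if (n_samples < 2) stop("n_samples must be >= 2")
  req <- function(df, cols, what) {
    if (!is.data.frame(df) || !all(cols %in% names(df)))
      stop(sprintf("%s must be a data.frame with columns %s",
                   what, paste(cols, collapse = ", ")))
  }
  req(snp_specs, c("snp_id", "chrom", "pos", "maf"), "snp_specs")
  req(probe_specs, c("probe_id", "chrom", "pos", "base_level"), "probe_specs")
  if (!"risk_allele" %in% names(snp_specs)) snp_specs$risk_allele <- "A"
  if (anyDuplicated(snp_specs$snp_id)) stop("duplicated snp_id in manifest")
  if (anyDuplicated(probe_specs$probe_id)) stop("duplicated probe_id in manifest")
  if (any(snp_specs$maf <= 0 | snp_specs$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  if (any(snp_specs$pos <= 0) || any(probe_specs$pos <= 0))
    stop("positions must be positive")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (sex_prob < 0 || sex_prob > 1) stop("sex_prob must lie in [0, 1]")
  if (length(weight_probs) != 3 || any(weight_probs < 0) ||
      abs(sum(weight_probs) - 1) > 1e-8)
    stop("weight_probs must be 3 nonnegative values summing to 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  if (!is.null(effect_specs)) {
    req(effect_specs, c("snp_id", "probe_id", "delta"), "effect_specs")
    bad <- !(effect_specs$snp_id %in% snp_specs$snp_id) |
      !(effect_specs$probe_id %in% probe_specs$probe_id)
    if (any(bad))
      stop("effect_specs references unknown ids: ",
           paste(effect_specs$snp_id[bad], effect_specs$probe_id[bad],
                 sep = "/", collapse = ", "))
  }
  if (!all(reference_probe_ids %in% probe_specs$probe_id))
    stop("reference_probe_ids must be a subset of the probe manifest")
  if (!is.null(celltype_offsets)) {
    celltype_offsets <- as.matrix(celltype_offsets)
    if (nrow(celltype_offsets) != nrow(probe_specs) ||
        ncol(celltype_offsets) != length(dirichlet_alpha))
      stop("celltype_offsets must be probes x cell-types")
    rownames(celltype_offsets) <- probe_specs$probe_id
  }
  if (!is.null(covariate_effects))
    req(covariate_effects, c("probe_id", "sex", "age", "weight"),
        "covariate_effects")
  structure(list(
    n_samples = as.integer(n_samples),
    snp_specs = snp_specs, probe_specs = probe_specs,
    effect_specs = effect_specs, covariate_effects = covariate_effects,
    celltype_offsets = celltype_offsets,
    reference_probe_ids = reference_probe_ids,
    noise_sd = noise_sd, dirichlet_alpha = dirichlet_alpha,
    sex_prob = sex_prob, age_range = age_range, weight_probs = weight_probs,
    missing_rate = missing_rate, detection_fail_rate = detection_fail_rate,
    chrom_lengths = chrom_lengths, seed = as.integer(seed)),
    class = "sim_config")
}

# Per-generator RNG streams derived from the config seed so that each stage
# is reproducible on its own and stages stay independent.
.sim_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% .Machine$integer.max)
}

#' Generate the sample covariate table
#'
#' Sex is Bernoulli (female = 1, male = 0), age uniform over the configured
#' range, and weight category multinomial over
#' normal weight = 0 / overweight = 1 / obese = 2.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with `sample_id`, `sex`, `age`, `weight_category`.
#' @export
gen_samples <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, 0L)
  n <- config$n_samples
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    sex = rbinom(n, 1, config$sex_prob),
    age = runif(n, config$age_range[1], config$age_range[2]),
    weight_category = sample(0:2, n, replace = TRUE,
                             prob = config$weight_probs),
    stringsAsFactors = FALSE)
}

#' Generate risk-allele dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are Binomial(2, maf) per SNP, counting risk alleles, with
#' optional missingness injected completely at random.
#'
#' @param config a [sim_config()] object.
#' @return integer matrix samples x SNPs with NA for missing genotypes.
#' @export
gen_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, 1L)
  n <- config$n_samples
  snps <- config$snp_specs
  G <- vapply(snps$maf, function(m) rbinom(n, 2L, m), integer(n))
  dim(G) <- c(n, nrow(snps))
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(G)) < config$missing_rate, nrow = n)
    G[miss] <- NA_integer_
  }
  dimnames(G) <- list(sprintf("S%04d", seq_len(n)), snps$snp_id)
  G
}

# Dirichlet draws via normalised gammas.
.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  w <- x / rowSums(x)
  colnames(w) <- names(alpha)
  w
}

#' Generate the methylation matrix with planted cis effects
#'
#' Builds M values per probe from the base level, the cell-mixture term
#' (composition weights times per-cell-type logit offsets), per-probe
#' covariate effects, the planted additive genotype effect, and Gaussian
#' noise; converts to beta values; and simulates a detection p-value matrix
#' (Beta(0.1, 100) for passing entries, Uniform(0,1) for injected failures).
#'
#' @param config a [sim_config()] object.
#' @param covariates output of [gen_samples()].
#' @param genotypes output of [gen_genotypes()].
#' @return list with `beta` (samples x probes), `detection_p`
#'   (same shape), and `ground_truth` (planted effects, true cell
#'   compositions, reference probe ids).
#' @export
gen_methylation <- function(config, covariates, genotypes) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  if (nrow(covariates) != n || nrow(genotypes) != n)
    stop("covariates/genotypes do not match the configured sample count")
  .sim_seed(config, 2L)
  probes <- config$probe_specs
  p <- nrow(probes)

  W <- .rdirichlet(n, config$dirichlet_alpha)
  rownames(W) <- covariates$sample_id

  M <- matrix(rep(probes$base_level, each = n), nrow = n)
  if (!is.null(config$celltype_offsets))
    M <- M + W %*% t(config$celltype_offsets)

  if (!is.null(config$covariate_effects)) {
    ce <- config$covariate_effects
    idx <- match(ce$probe_id, probes$probe_id)
    X <- cbind(covariates$sex, covariates$age, covariates$weight_category)
    B <- matrix(0, nrow = 3, ncol = p)
    B[, idx] <- t(as.matrix(ce[, c("sex", "age", "weight")]))
    M <- M + X %*% B
  }

  true_effects <- data.frame(snp_id = character(), probe_id = character(),
                             delta = numeric(), stringsAsFactors = FALSE)
  if (!is.null(config$effect_specs)) {
    es <- config$effect_specs
    for (i in seq_len(nrow(es))) {
      j <- match(es$probe_id[i], probes$probe_id)
      g <- genotypes[, es$snp_id[i]]
      g[is.na(g)] <- 0  # planted effect acts through observed alleles only
      M[, j] <- M[, j] + es$delta[i] * g
    }
    true_effects <- es[, c("snp_id", "probe_id", "delta")]
  }

  M <- M + matrix(rnorm(n * p, sd = config$noise_sd), nrow = n)
  beta <- 2^M / (2^M + 1)
  dimnames(beta) <- list(covariates$sample_id, probes$probe_id)

  fail <- matrix(runif(n * p) < config$detection_fail_rate, nrow = n)
  detp <- matrix(rbeta(n * p, 0.1, 100), nrow = n)
  detp[fail] <- runif(sum(fail))
  dimnames(detp) <- dimnames(beta)

  list(beta = beta, detection_p = detp,
       ground_truth = list(true_effects = true_effects,
                           true_compositions = W,
                           reference_probe_ids = config$reference_probe_ids))
}

#' Generate annotation fixtures with known ground truth
#'
#' Produces non-overlapping toy gene models with strand (so a TSS), a
#' per-tissue tiling of each chromosome into the seven collapsed
#' chromatin-state categories, paired interaction anchors (some planted to
#' overlap probe positions and gene promoters), and an enhancer interval
#' set. Ground-truth memberships for every probe are recorded by direct
#' position arithmetic, independently of the annotation engine.
#'
#' @param config a [sim_config()] object.
#' @param n_genes genes per chromosome.
#' @param tissues character vector of tissue labels for the segmentations.
#' @param interaction_counts named integer vector, probe_id -> number of
#'   anchor pairs planted to overlap that probe.
#' @param promoter_window bp around the TSS counted as promoter in the
#'   recorded truth.
#' @return list with `genes`, `states` (list per tissue), `interactions`
#'   (BEDPE-style data.frame), `enhancers`, and `truth` (per-probe region
#'   class, state category per tissue, interaction count).
#' @export
gen_annotation <- function(config, n_genes = 12,
                           tissues = c("pbmc", "liver"),
                           interaction_counts = NULL,
                           promoter_window = 1500) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, 3L)
  probes <- config$probe_specs
  chroms <- names(config$chrom_lengths)

  genes_l <- list()
  states_l <- stats::setNames(vector("list", length(tissues)), tissues)
  for (ti in tissues) states_l[[ti]] <- list()
  for (chrom in chroms) {
    len <- config$chrom_lengths[[chrom]]
    # non-overlapping genes: carve the chromosome into slots, one gene each
    slots <- floor(seq(1, len, length.out = n_genes + 1))
    gs <- ge <- integer(n_genes); strand <- character(n_genes)
    for (i in seq_len(n_genes)) {
      a <- slots[i]; b <- slots[i + 1] - 2000
      gs[i] <- floor(runif(1, a, a + (b - a) * 0.3))
      ge[i] <- floor(runif(1, gs[i] + 2000, max(gs[i] + 2001, b)))
      strand[i] <- sample(c("+", "-"), 1)
    }
    genes_l[[chrom]] <- data.frame(
      chrom = chrom, start = gs, end = ge,
      gene_id = sprintf("%s_gene%02d", chrom, seq_len(n_genes)),
      score = 0, strand = strand, stringsAsFactors = FALSE)
    # per-tissue tiling: random breakpoints partition [1, len]
    for (ti in tissues) {
      k <- max(20L, n_genes * 4L)
      bp <- sort(sample(seq(2, len - 1), k))
      st <- c(1, bp); en <- c(bp - 1, len)
      states_l[[ti]][[chrom]] <- data.frame(
        chrom = chrom, start = st, end = en,
        category = sample(STATE_CATEGORIES, k + 1, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes_l)
  rownames(genes) <- NULL
  states <- lapply(states_l, function(x) {
    d <- do.call(rbind, x); rownames(d) <- NULL; d
  })

  tss <- ifelse(genes$strand == "+", genes$start, genes$end)

  # interactions: planted pairs whose left anchor covers a probe, partner
  # anchors alternating between promoter hits and plain intergenic spans
  inter <- NULL
  if (!is.null(interaction_counts) && length(interaction_counts)) {
    rows <- list()
    for (pid in names(interaction_counts)) {
      k <- interaction_counts[[pid]]
      if (k == 0) next
      pi_ <- match(pid, probes$probe_id)
      if (is.na(pi_)) stop("interaction_counts names unknown probe: ", pid)
      chrom <- probes$chrom[pi_]; pos <- probes$pos[pi_]
      gsel <- which(genes$chrom == chrom)
      for (j in seq_len(k)) {
        # internal convention: 1-based inclusive, like the gene models
        left <- c(max(1, pos - 500), pos + 500)
        if (j %% 2 == 1 && length(gsel)) {
          g <- gsel[1 + (j %% length(gsel))]
          right <- c(max(1, tss[g] - 200), tss[g] + 200)
          hits_prom <- TRUE
        } else {
          far <- min(pos + 50000, config$chrom_lengths[[chrom]] - 1000)
          right <- c(far, far + 400)
          hits_prom <- FALSE
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom1 = chrom, start1 = left[1], end1 = left[2],
          chrom2 = chrom, start2 = right[1], end2 = right[2],
          strength = round(runif(1, 1, 10), 2),
          promoter_partner = hits_prom, stringsAsFactors = FALSE)
      }
    }
    inter <- do.call(rbind, rows)
  } else {
    inter <- data.frame(chrom1 = character(), start1 = integer(),
                        end1 = integer(), chrom2 = character(),
                        start2 = integer(), end2 = integer(),
                        strength = numeric(), promoter_partner = logical(),
                        stringsAsFactors = FALSE)
  }

  # enhancers: the enhancer-category intervals of the first tissue
  enh <- states[[1]][states[[1]]$category == "enhancer",
                     c("chrom", "start", "end")]
  rownames(enh) <- NULL

  # ground truth by direct arithmetic on 1-based positions
  region <- character(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    on_chr <- genes$chrom == probes$chrom[i]
    d_tss <- abs(probes$pos[i] - tss)
    in_prom <- any(on_chr & d_tss <= promoter_window)
    in_body <- any(on_chr & probes$pos[i] >= genes$start &
                     probes$pos[i] <= genes$end)
    region[i] <- if (in_prom && in_body) "ambiguous"
    else if (in_prom) "promoter"
    else if (in_body) "gene_body" else "intergenic"
  }
  state_truth <- sapply(tissues, function(ti) {
    seg <- states[[ti]]
    vapply(seq_len(nrow(probes)), function(i) {
      hit <- seg$chrom == probes$chrom[i] & seg$start <= probes$pos[i] &
        seg$end >= probes$pos[i]
      seg$category[which(hit)[1]]
    }, character(1))
  })
  icount <- stats::setNames(integer(nrow(probes)), probes$probe_id)
  if (!is.null(interaction_counts))
    icount[names(interaction_counts)] <- as.integer(interaction_counts)

  list(genes = genes, states = states, interactions = inter,
       enhancers = enh,
       truth = list(region_class = stats::setNames(region, probes$probe_id),
                    state_category = state_truth,
                    interaction_count = icount))
}

#' Generate a complete synthetic dataset
#'
#' Runs all generators in sequence from one configuration: covariates,
#' genotypes, methylation (+ detection p-values and ground truth), and
#' annotation fixtures.
#'
#' @param config a [sim_config()] object.
#' @param annotation logical; also generate annotation fixtures.
#' @param ... passed to [gen_annotation()].
#' @return list with `config`, `covariates`, `genotypes`, `beta`,
#'   `detection_p`, `ground_truth`, and optionally `annotation`.
#' @export
simulate_dataset <- function(config, annotation = FALSE, ...) {
  cov <- gen_samples(config)
  G <- gen_genotypes(config)
  meth <- gen_methylation(config, cov, G)
  out <- list(config = config, covariates = cov, genotypes = G,
              beta = meth$beta, detection_p = meth$detection_p,
              ground_truth = meth$ground_truth)
  if (annotation) out$annotation <- gen_annotation(config, ...)
  out
}

#' Isolated-pair simulation configuration
#'
#' Builds a cohort of `n_pairs` independent SNP-CpG pairs, each in its own
#' genomic block so the cis pairing yields exactly one probe per SNP. The
#' first `n_true` pairs carry a planted additive effect of `delta` M-units
#' per risk allele; the rest are null. A cell-type reference panel and mild
#' covariate effects are included so the scan exercises the full adjusted
#' model. This is the workhorse for calibration, FDR and parameter-recovery
#' simulations.
#'
#' @param n_pairs number of SNP-CpG pairs.
#' @param n_true number of pairs with a planted effect.
#' @param delta planted effect size, M-units per risk allele.
#' @param n_samples cohort size.
#' @param maf minor (risk) allele frequency shared by all SNPs.
#' @param noise_sd residual SD on the M scale.
#' @param n_reference_probes size of the cell-type reference panel.
#' @param seed integer seed.
#' @return a `sim_config` object; planted pairs are recorded in its
#'   `effect_specs`.
#' @export
sim_pairs_config <- function(n_pairs, n_true = 0, delta = 0,
                             n_samples = 350, maf = 0.3, noise_sd = 0.5,
                             n_reference_probes = 43, seed = 1L) {
  stopifnot(n_true <= n_pairs)
  set.seed(seed %% .Machine$integer.max)
  block <- 1.1e6
  base <- (seq_len(n_pairs) - 1) * block
  snps <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(n_pairs)),
    chrom = "chrS", pos = base + 5e5,
    risk_allele = "A", maf = maf, stringsAsFactors = FALSE)
  ref_pos <- n_pairs * block + 6e5 +
    floor(seq(1, 4e5, length.out = n_reference_probes))
  probes <- data.frame(
    probe_id = c(sprintf("cg%06d", seq_len(n_pairs)),
                 sprintf("cgref%03d", seq_len(n_reference_probes))),
    chrom = "chrS",
    pos = c(base + 5.002e5, ref_pos),
    base_level = rnorm(n_pairs + n_reference_probes, 0, 1),
    stringsAsFactors = FALSE)
  ref_ids <- probes$probe_id[-seq_len(n_pairs)]
  cell_types <- c("gran", "cd4t", "cd8t", "bcell", "nk", "mono")
  v1 <- c(1, -0.9, -0.9, -0.8, -0.7, 0.2)
  v2 <- c(-0.2, -0.3, -0.1, 0.4, 0.3, 1)
  off <- matrix(rnorm(nrow(probes) * length(cell_types), 0, 0.3),
                nrow(probes), length(cell_types),
                dimnames = list(probes$probe_id, cell_types))
  off[ref_ids, ] <- outer(rnorm(n_reference_probes, 0, 6), v1) +
    outer(rnorm(n_reference_probes, 0, 3), v2)
  covef <- data.frame(probe_id = probes$probe_id,
                      sex = rnorm(nrow(probes), 0, 0.1),
                      age = rnorm(nrow(probes), 0, 0.01),
                      weight = rnorm(nrow(probes), 0, 0.05),
                      stringsAsFactors = FALSE)
  effects <- NULL
  if (n_true > 0)
    effects <- data.frame(snp_id = snps$snp_id[seq_len(n_true)],
                          probe_id = probes$probe_id[seq_len(n_true)],
                          delta = delta, stringsAsFactors = FALSE)
  sim_config(n_samples = n_samples, snp_specs = snps, probe_specs = probes,
             effect_specs = effects, covariate_effects = covef,
             celltype_offsets = off, reference_probe_ids = ref_ids,
             noise_sd = noise_sd,
             dirichlet_alpha = stats::setNames(
               c(10, 4, 2.5, 1.5, 1.5, 1.5), cell_types),
             chrom_lengths = c(chrS = (n_pairs + 1) * block + 1e6),
             seed = seed)
}

#' Run the adjusted scan on an isolated-pair configuration
#'
#' Convenience wrapper: simulates the cohort of a [sim_pairs_config()],
#' converts to M values, builds the cell surrogate, enumerates cis pairs
#' and runs [run_scan()]. No QC filtering is applied (the generated data
#' have no failing probes by construction at the default failure rate of
#' zero used here).
#'
#' @param config a `sim_config` from [sim_pairs_config()].
#' @param ... passed to [run_scan()].
#' @return the [run_scan()] result list, with the simulated dataset
#'   attached as `dataset`.
#' @export
scan_simulated_pairs <- function(config, ...) {
  ds <- simulate_dataset(config)
  m <- beta_to_m(ds$beta)
  surr <- cell_surrogate(m, config$reference_probe_ids)
  pairs <- pair_cis(config$snp_specs, config$probe_specs)
  pairs <- pairs[!grepl("^cgref", pairs$probe_id), , drop = FALSE]
  out <- run_scan(m, ds$covariates, surr, ds$genotypes, pairs, ...)
  out$dataset <- ds
  out
}

#' Study-scale simulation configuration
#'
#' Convenience builder emulating the structure of a blood-cohort discovery
#' dataset: by default 355 samples, 52 SNPs spread along a synthetic
#' chromosome, candidate CpG probes within +/-500 kb of each SNP, a 43-probe
#' cell-type discriminating reference panel with low-rank cell-type offsets,
#' blood-like Dirichlet cell mixtures, and optional planted effects.
#'
#' The cell-type offsets of the reference panel are built from two latent
#' contrasts (a granulocyte-versus-lymphoid axis and a monocyte axis) so
#' that the panel's variance is concentrated on two principal components,
#' as expected of a composition surrogate.
#'
#' @param n_samples,n_snps,probes_per_snp cohort dimensions.
#' @param n_reference_probes size of the cell-type reference panel.
#' @param effect_specs optional planted effects (see [sim_config()]).
#' @param noise_sd residual SD on the M scale.
#' @param offset_scale amplitude of the reference-panel cell-type offsets
#'   (M units).
#' @param covariate_sd SDs of the per-probe sex/age/weight coefficients.
#' @param seed integer seed.
#' @param ... passed on to [sim_config()].
#' @return a `sim_config` object.
#' @export
sim_study_config <- function(n_samples = 355, n_snps = 52,
                             probes_per_snp = 160,
                             n_reference_probes = 43,
                             effect_specs = NULL,
                             noise_sd = 0.5,
                             offset_scale = 6,
                             covariate_sd = c(sex = 0.1, age = 0.01,
                                              weight = 0.05),
                             seed = 1L, ...) {
  set.seed(seed %% .Machine$integer.max)
  chrom_len <- max(2e6, (n_snps + 1) * 1.1e6)
  snp_pos <- floor(seq(6e5, chrom_len - 6e5, length.out = n_snps))
  snps <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(n_snps)),
    chrom = "chrS", pos = snp_pos,
    risk_allele = sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
    maf = runif(n_snps, 0.05, 0.5), stringsAsFactors = FALSE)
  # candidate probes scattered in the cis window of each SNP
  ppos <- unlist(lapply(snp_pos, function(s)
    sort(floor(runif(probes_per_snp, max(1, s - 5e5), s + 5e5)))))
  ppos <- unique(ppos)
  n_cand <- length(ppos)
  # reference panel parked outside the cis windows so QC never removes it
  ref_pos <- floor(seq(1e4, 5e5, length.out = n_reference_probes))
  probes <- data.frame(
    probe_id = c(sprintf("cg%06d", seq_len(n_cand)),
                 sprintf("cgref%03d", seq_len(n_reference_probes))),
    chrom = "chrS", pos = c(ppos, ref_pos),
    base_level = rnorm(n_cand + n_reference_probes, 0, 1.5),
    stringsAsFactors = FALSE)
  ref_ids <- probes$probe_id[(n_cand + 1):(n_cand + n_reference_probes)]

  cell_types <- c("gran", "cd4t", "cd8t", "bcell", "nk", "mono")
  v1 <- c(1, -0.9, -0.9, -0.8, -0.7, 0.2)   # myeloid vs lymphoid
  v2 <- c(-0.2, -0.3, -0.1, 0.4, 0.3, 1)    # monocyte axis
  off <- matrix(0, nrow(probes), length(cell_types),
                dimnames = list(probes$probe_id, cell_types))
  a1 <- rnorm(n_reference_probes, 0, offset_scale)
  a2 <- rnorm(n_reference_probes, 0, offset_scale / 2)
  off[ref_ids, ] <- outer(a1, v1) + outer(a2, v2) +
    matrix(rnorm(n_reference_probes * length(cell_types), 0, 0.2),
           n_reference_probes)
  # candidate probes carry a mild composition signal, as bulk blood does
  off[seq_len(n_cand), ] <- matrix(
    rnorm(n_cand * length(cell_types), 0, 0.3), n_cand)

  covef <- data.frame(
    probe_id = probes$probe_id,
    sex = rnorm(nrow(probes), 0, covariate_sd[["sex"]]),
    age = rnorm(nrow(probes), 0, covariate_sd[["age"]]),
    weight = rnorm(nrow(probes), 0, covariate_sd[["weight"]]),
    stringsAsFactors = FALSE)

  sim_config(n_samples = n_samples, snp_specs = snps, probe_specs = probes,
             effect_specs = effect_specs, covariate_effects = covef,
             celltype_offsets = off, reference_probe_ids = ref_ids,
             noise_sd = noise_sd,
             dirichlet_alpha = stats::setNames(
               c(10, 4, 2.5, 1.5, 1.5, 1.5), cell_types),
             chrom_lengths = c(chrS = chrom_len), seed = seed, ...)
}
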