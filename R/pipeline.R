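# Pipeline orchestration: configuration, the simulate -> preprocess ->
# scan -> annotate -> enrich -> power stage sequence, and the per-SNP
# report. Every analysis threshold lives in the defaults YAML shipped with
# the package, never inline in code.

#' Load a pipeline configuration
#'
#' Starts from the packaged defaults (`inst/extdata/default_config.yaml`),
#' then overlays a user YAML file and/or a list of overrides. Thresholds
#' are range-checked.
#'
#' @param path optional YAML file with overrides.
#' @param overrides optional named list of overrides (nested lists merge
#'   field-wise).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                          package = "meqtlscan"))
  merge2 <- function(base, extra) {
    for (k in names(extra)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(extra[[k]]))
        merge2(base[[k]], extra[[k]]) else extra[[k]]
    }
    base
  }
  cfg <- defaults
  if (!is.null(path)) cfg <- merge2(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge2(cfg, overrides)
  th <- cfg$thresholds
  stopifnot(th$window > 0,
            th$detection_fraction > 0, th$detection_fraction <= 1,
            th$detection_p > 0, th$detection_p < 1,
            th$reference_range_min >= 0, th$reference_range_min <= 1,
            th$outlier_n_pcs >= 1, th$outlier_z > 0,
            th$min_homozygote_count >= 0,
            th$q_threshold > 0, th$q_threshold < 1)
  structure(cfg, class = "pipeline_config")
}

.write_stage <- function(x, dir, name) {
  path <- file.path(dir, name)
  if (is.matrix(x)) write_matrix_tsv(x, path)
  else write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> scan -> annotate -> enrich -> power
#' with the parameters of a [pipeline_config()], writing every stage table
#' under `out_dir` and returning a run manifest (paths, md5 hashes, stage
#' counts, parameter echo). Reruns with the same configuration reproduce
#' byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `config`, `files` (named paths), `hashes`,
#'   `counts`, and the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir = tempfile("meqtl_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  sim <- config$simulation
  stage <- "simulate"
  res <- tryCatch({
    effects <- NULL
    sc0 <- sim_study_config(n_samples = sim$n_samples,
                            n_snps = sim$n_snps,
                            probes_per_snp = sim$probes_per_snp,
                            noise_sd = sim$noise_sd, seed = config$seed)
    if (sim$n_true_effects > 0) {
      # plant each effect on the probe nearest its SNP
      snps <- sc0$snp_specs[seq_len(min(sim$n_true_effects,
                                        nrow(sc0$snp_specs))), ]
      probe_idx <- vapply(snps$pos, function(p)
        which.min(abs(sc0$probe_specs$pos - p)), integer(1))
      effects <- data.frame(snp_id = snps$snp_id,
                            probe_id = sc0$probe_specs$probe_id[probe_idx],
                            delta = sim$delta, stringsAsFactors = FALSE)
    }
    cfg <- sim_study_config(n_samples = sim$n_samples, n_snps = sim$n_snps,
                            probes_per_snp = sim$probes_per_snp,
                            noise_sd = sim$noise_sd,
                            effect_specs = effects, seed = config$seed)
    ds <- simulate_dataset(cfg, annotation = TRUE,
                           tissues = config$annotation$tissues)

    stage <- "preprocess"
    flags <- data.frame(probe_id = cfg$probe_specs$probe_id,
                        chrom = cfg$probe_specs$chrom,
                        pos = cfg$probe_specs$pos,
                        is_sex_chromosome = FALSE,
                        is_cross_reactive = FALSE,
                        has_maf_gt1pct_snp = FALSE,
                        stringsAsFactors = FALSE)
    pp <- preprocess_methylation(
      ds$beta, ds$detection_p, flags,
      reference_probe_ids = cfg$reference_probe_ids,
      min_fraction = th$detection_fraction, p_threshold = th$detection_p,
      min_range = th$reference_range_min,
      n_pcs = th$outlier_n_pcs, z_threshold = th$outlier_z)
    keep <- rownames(ds$beta) %in% pp$retained_samples
    cov <- ds$covariates[keep, , drop = FALSE]
    G <- ds$genotypes[keep, , drop = FALSE]

    stage <- "scan"
    pairs <- pair_cis(cfg$snp_specs, cfg$probe_specs, window = th$window)
    scan <- run_scan(pp$m_values, cov, pp$surrogate, G, pairs,
                     q_threshold = th$q_threshold,
                     min_homozygote_count = th$min_homozygote_count)

    stage <- "annotate"
    tested_ids <- unique(scan$results$probe_id)
    pm <- cfg$probe_specs[cfg$probe_specs$probe_id %in% tested_ids, ]
    ann <- annotate_probes(pm, ds$annotation$genes, ds$annotation$states,
                           ds$annotation$interactions,
                           ds$annotation$enhancers,
                           promoter_window = th$promoter_window)

    stage <- "enrich"
    assoc_ids <- unique(scan$significant$probe_id)
    enr <- NULL
    if (length(assoc_ids) > 0) {
      reg <- sapply(c("promoter", "gene_body", "intergenic", "ambiguous"),
                    function(cl) ann$class == cl)
      rownames(reg) <- ann$probe_id
      enr_genomic <- fisher_enrichment(assoc_ids, ann$probe_id, reg,
                                       background = config$enrichment$background)
      state_cols <- grep("^state_", names(ann), value = TRUE)
      smemb <- do.call(cbind, lapply(state_cols, function(cn) {
        m <- sapply(STATE_CATEGORIES, function(cat)
          !is.na(ann[[cn]]) & ann[[cn]] == cat)
        colnames(m) <- paste(sub("^state_", "", cn), STATE_CATEGORIES,
                             sep = ":")
        m
      }))
      rownames(smemb) <- ann$probe_id
      enr_states <- fisher_enrichment(assoc_ids, ann$probe_id, smemb,
                                      background = config$enrichment$background)
      enr <- rbind(cbind(family = "genomic", enr_genomic),
                   cbind(family = "states", enr_states))
      if ("in_enhancer" %in% names(ann)) {
        em <- matrix(ann$in_enhancer, ncol = 1,
                     dimnames = list(ann$probe_id, "enhancer_set"))
        enr <- rbind(enr, cbind(family = "enhancers",
                                fisher_enrichment(
                                  assoc_ids, ann$probe_id, em,
                                  background = config$enrichment$background)))
      }
    }

    stage <- "power"
    pw <- NULL
    if (nrow(scan$significant) > 0) {
      pw <- scan$significant[, c("snp_id", "probe_id", "partial_r2")]
      pw$replication_n <- config$power$replication_n
      pw$power <- power_from_r2(pw$partial_r2, config$power$replication_n,
                                n_model_terms = config$power$n_model_terms,
                                alpha = config$power$alpha)
    }
    list(dataset = ds, preprocess = pp, scan = scan, annotation = ann,
         enrichment = enr, power = pw)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  files <- c(
    covariates = .write_stage(res$dataset$covariates, out_dir,
                              "covariates.tsv"),
    genotypes = .write_stage(res$dataset$genotypes, out_dir,
                             "genotypes.tsv"),
    scan_results = .write_stage(res$scan$results, out_dir,
                                "scan_results.tsv"),
    significant = .write_stage(res$scan$significant, out_dir,
                               "scan_significant.tsv"),
    annotation = .write_stage(res$annotation, out_dir, "annotation.tsv"))
  if (!is.null(res$enrichment))
    files["enrichment"] <- .write_stage(res$enrichment, out_dir,
                                        "enrichment.tsv")
  if (!is.null(res$power))
    files["power"] <- .write_stage(res$power, out_dir, "power.tsv")
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  files["config"] <- cfg_path
  hashes <- tools::md5sum(files)
  names(hashes) <- names(files)
  manifest <- list(
    config = config, files = files, hashes = hashes,
    counts = list(
      n_samples_retained = length(res$preprocess$retained_samples),
      n_probes_retained = ncol(res$preprocess$m_values),
      n_pairs_tested = nrow(res$scan$results),
      n_significant = nrow(res$scan$significant),
      n_snps_significant = length(unique(res$scan$significant$snp_id))))
  jsonlite::write_json(
    manifest[c("hashes", "counts")],
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  c(manifest, res[c("scan", "annotation", "enrichment", "power",
                    "preprocess", "dataset")])
}

#' Render a per-SNP summary report
#'
#' One section per SNP: its significant CpGs with distance, region class,
#' chromatin states per tissue and interaction counts; SNPs with no
#' significant CpG are reported as such.
#'
#' @param scan_results full result table from [run_scan()].
#' @param annotations probe annotation table from [annotate_probes()].
#' @param enrichments optional enrichment table.
#' @return list with `summary` (per-SNP data.frame: counts and median
#'   distance) and `text` (character vector, the rendered report).
#' @export
render_report <- function(scan_results, annotations, enrichments = NULL) {
  snps <- unique(scan_results$snp_id)
  lines <- character()
  summ <- list()
  for (s in snps) {
    sig <- scan_results[scan_results$snp_id == s &
                          scan_results$significant, , drop = FALSE]
    lines <- c(lines, sprintf("== %s ==", s))
    if (nrow(sig) == 0) {
      lines <- c(lines, "  none")
      summ[[s]] <- data.frame(snp_id = s, n_significant = 0L,
                              median_distance = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    a <- annotations[match(sig$probe_id, annotations$probe_id), ]
    for (i in seq_len(nrow(sig))) {
      lines <- c(lines, sprintf(
        "  %s  dist=%d bp  coef=%.3f  q=%.2e  class=%s%s",
        sig$probe_id[i], sig$distance[i], sig$coef_genotype[i],
        sig$q_value[i], a$class[i],
        if ("n_interactions" %in% names(a))
          sprintf("  interactions=%d", a$n_interactions[i]) else ""))
    }
    summ[[s]] <- data.frame(snp_id = s, n_significant = nrow(sig),
                            median_distance = stats::median(sig$distance),
                            stringsAsFactors = FALSE)
  }
  if (!is.null(enrichments)) {
    sig_e <- enrichments[enrichments$q_value < 0.05, , drop = FALSE]
    lines <- c(lines, "== enrichment (q < 0.05) ==",
               if (nrow(sig_e)) sprintf(
                 "  %s/%s OR=%.2f q=%.2e", sig_e$family, sig_e$category,
                 sig_e$odds_ratio, sig_e$q_value) else "  none")
  }
  list(summary = do.call(rbind, summ), text = lines)
}
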