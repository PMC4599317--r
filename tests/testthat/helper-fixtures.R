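# Small fixtures built in code.

# Minimal manifests: 2 SNPs and 5 probes on one chromosome.
tiny_config <- function(n_samples = 10, seed = 1, ...) {
  snps <- data.frame(snp_id = c("rsA", "rsB"), chrom = "chr1",
                     pos = c(100000L, 900000L), risk_allele = "A",
                     maf = c(0.3, 0.4), stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = paste0("cg", 1:5), chrom = "chr1",
                       pos = c(95000L, 160000L, 400000L, 880000L, 950000L),
                       base_level = 0, stringsAsFactors = FALSE)
  sim_config(n_samples = n_samples, snp_specs = snps, probe_specs = probes,
             seed = seed, ...)
}

# Simulated covariates/surrogate/dosage for single-pair model fits.
random_design <- function(n, seed) {
  set.seed(seed)
  list(cov = data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 14, 34),
                        weight_category = sample(0:2, n, replace = TRUE)),
       sur = list(pc1 = rnorm(n), pc2 = rnorm(n)),
       g = rbinom(n, 2, runif(1, 0.15, 0.5)))
}

# Toy gene models: geneA on +, geneB on -.
toy_genes <- function() {
  data.frame(chrom = "chr1",
             start = c(10000L, 50000L), end = c(20000L, 60000L),
             gene_id = c("geneA", "geneB"), score = 0,
             strand = c("+", "-"), stringsAsFactors = FALSE)
}
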