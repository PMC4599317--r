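# meqtlscan

Cis-meQTL discovery for candidate SNPs on Illumina 450K-style methylation
data, with covariate and cell-composition adjustment, Storey q-value FDR
control, and genomic-context enrichment.

## What it does, and for whom

A methylation quantitative trait locus (meQTL) is a genetic variant whose
alleles associate with DNA methylation at a nearby CpG site. Given a
candidate SNP panel, a beta-value matrix, sample covariates and annotation
tracks, `meqtlscan`:

1. **Preprocesses** the methylation matrix: probe exclusion (missing
   betas, detection-p failures, sex chromosomes, cross-reactive and
   SNP-containing probes), beta→M conversion, PCA-based sample outlier
   exclusion, and a two-principal-component surrogate for blood cell-type
   composition built from a reference CpG panel.
2. **Scans** all SNP–CpG pairs within ±500 kb. For each CpG site *k*:

   *M*<sub>k</sub> = *a*<sub>k</sub> + *b*<sub>kS</sub>·S + *b*<sub>kA</sub>·A +
   *b*<sub>kW</sub>·W + *b*<sub>kG</sub>·G + *b*<sub>kPC1</sub>·PC1 +
   *b*<sub>kPC2</sub>·PC2 + ε<sub>k</sub>

   with S = sex, A = age, W = weight category (0/1/2), G = risk-allele
   dosage (0/1/2, rare homozygote classes under 10 collapsed into the
   heterozygotes), PC1/PC2 the cell surrogate. The genotype term is tested
   with the likelihood ratio statistic *n*·ln(RSS₀/RSS₁) ~ χ²₁ and its
   effect size reported as the partial R² = (RSS₀ − RSS₁)/RSS₀. Storey
   q-values (smoother pi0) control the FDR over all tested pairs;
   associations are called at q < 0.05.
3. **Annotates and tests enrichment** of associated CpGs against gene
   models (promoter = TSS ± 1500 bp / gene body / ambiguous / intergenic),
   chromatin-state segmentations collapsed to seven categories, enhancer
   sets, and ChIA-PET interaction anchors — Fisher exact tests against the
   tested background, Mann–Whitney for interaction counts.
4. **Computes replication power** via the noncentral-F formulation with
   Cohen's f2 = R²/(1 − R²).

A first-class synthetic-data generator (`sim_config()`,
`sim_study_config()`, `sim_pairs_config()`, `simulate_dataset()`) produces
cohorts with planted effects and full ground truth, so the entire pipeline
is testable without cohort downloads.

## Worked example

Simulate 20 isolated SNP–CpG pairs (350 samples, three planted effects of
0.8 M-units per risk allele) and scan them:

```r
library(meqtlscan)
cfg  <- sim_pairs_config(20, n_true = 3, delta = 0.8, n_samples = 350, seed = 42)
scan <- scan_simulated_pairs(cfg)
scan$significant[, c("snp_id", "probe_id", "distance", "coef_genotype",
                     "p_value", "q_value", "partial_r2")]
#>    snp_id probe_id distance coef_genotype  p_value  q_value partial_r2
#> 1 rs00001 cg000001      200         0.743 6.91e-56 3.68e-55      0.508
#> 2 rs00002 cg000002      200         0.805 5.29e-61 4.23e-60      0.540
#> 3 rs00003 cg000003      200         0.869 5.38e-62 8.60e-61      0.546
```

Exactly the three planted pairs are recovered; the coefficients estimate
the planted 0.8 M-units per risk allele, and the partial R² column says
each SNP explains ~50 % of the methylation variance left after the
covariates. Replication power for the top hit in a hypothetical cohort of
62:

```r
power_from_r2(scan$significant$partial_r2[1], n = 62)
#> [1] 1
```

The full pipeline (simulate → preprocess → scan → annotate → enrich →
power) runs from a YAML-configured driver:

```r
cfg <- pipeline_config()   # packaged defaults: 355 samples, 52 SNPs, ±500 kb
run <- run_pipeline(cfg, out_dir = "run1")
run$counts
report <- render_report(run$scan$results, run$annotation, run$enrichment)
```

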