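---
title: "Methods: cis-meQTL discovery with covariate and cell-composition adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-meQTL discovery with covariate and cell-composition adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtlscan)
```

# The problem

A methylation quantitative trait locus (meQTL) is a genetic variant whose
alleles associate with DNA methylation levels at a CpG site. `meqtlscan`
implements a *cis* discovery scan for candidate SNPs: each SNP is tested
against every CpG probe within a window (500 kb by default, boundary
inclusive) on the same chromosome, on methylation measured by an Illumina
450K-style array in a blood cohort. Blood is a cell mixture, and cell-type
proportions both vary across individuals and dominate bulk methylation, so
the scan adjusts for a composition surrogate alongside demographic
covariates.

# The association model

Methylation is analysed on the M scale, `M = log2(beta / (1 - beta))`,
which is closer to homoscedastic Gaussian than the bounded beta scale. For
each CpG site *k* and each SNP paired with it, the full model is

$$M_k = a_k + b_{kS} S + b_{kA} A + b_{kW} W + b_{kG} G
      + b_{kPC1} PC1 + b_{kPC2} PC2 + \varepsilon_k$$

with *S* sex (female = 1, male = 0), *A* age in years, *W* weight category
(normal weight = 0, overweight = 1, obese = 2, entered as a numeric trend),
*G* the risk-allele dosage (0/1/2), and *PC1*, *PC2* the cell-composition
surrogate. The genotype term is tested by comparing this fit with the
reduced model without *G*, using the Gaussian likelihood ratio statistic

$$\Lambda = n \,\ln\frac{RSS_{reduced}}{RSS_{full}} \sim \chi^2_1 ,$$

which is algebraically identical to twice the difference of maximised
Gaussian log-likelihoods of the two least-squares fits (the package's test
suite verifies this against `lmtest::lrtest` and an independently coded
log-likelihood oracle). The effect size reported is the partial
R^2^, `(RSS_reduced - RSS_full) / RSS_reduced`: the share of methylation
variance *not already explained by the covariates* that the genotype
explains. Because "variance explained by the SNP" is sometimes quoted
against total variance instead, the scan also emits a plain marginal R^2^
(squared correlation of M with dosage) without asserting that either is
the more meaningful summary; the partial form is what the testing
machinery uses.

## Genotype handling

Dosages count risk alleles. Samples with a missing genotype are dropped per
SNP (complete-case analysis). A homozygote class observed in fewer than 10
individuals is merged with the heterozygotes and the variable recoded to
two levels, which keeps the 1-df additive test but stops a handful of rare
homozygotes from leveraging the fit; 10 exactly is kept separate. A SNP
monomorphic after masking and collapsing is reported untestable rather
than failing the scan.

## Multiple testing

All testable pairs form a single q-value family. Storey q-values are
computed with the smoother pi0 estimate: `pi0(lambda) =
mean(p > lambda) / (1 - lambda)` on the grid 0.05–0.90 (step 0.05), fitted
with a df-3 smoothing spline and evaluated at the largest usable lambda,
clamped to (0, 1]. Lambdas at or beyond the largest observed p-value are
dropped — there the numerator is exactly zero and the raw estimate
degenerates — and if fewer than four grid points survive, pi0 falls back
to 1, which makes the q-values exactly Benjamini–Hochberg (that reduction
is asserted in the tests). An association is declared at q < 0.05.

# Preprocessing

* **Probe exclusion** removes probes with any missing beta value, probes
  with *strictly less than* 75 % of samples at detection p < 0.01, probes
  on sex chromosomes, cross-reactive probes, and probes containing common
  SNPs (the latter three as flags supplied by the user; the package does
  not ship an array annotation).
* **Variable probes** are chosen by the 95 % reference range — the
  difference between the 97.5th and 2.5th percentiles, computed with the
  linear-interpolation quantile (R type 7). No quantile convention is
  canonical here; type 7 is R's default and is documented rather than
  argued for. Retention is inclusive at the 0.20 threshold.
* **Sample outliers** are excluded on the first eight PCs of the
  variable-probe matrix: any sample farther than `z_threshold` SDs from a
  component's mean, on any of the eight, is dropped. "Outlier" has no
  standard definition on a PC; the package defaults to |z| > 3,
  configurable, and reports the offending component per excluded sample.
* **The cell surrogate** is the first two PCs of the M values of a
  reference panel of cell-type discriminating CpGs (an input list, 43 in
  the emulated design, never hard-coded). On blood-like simulated
  mixtures these two components carry over 70 % of the panel's variance
  and track the true compositions with canonical correlation above 0.99.

# The synthetic cohort generator

No generative model is given for real cohort data, so the generator's
distributions are explicit fixtures, not claims about any population:

* Covariates: sex Bernoulli(0.4 female), age uniform on 14–34 years,
  weight category multinomial (0.76, 0.20, 0.04) — matching the cohort
  structure the pipeline is designed for.
* Genotypes: Binomial(2, maf) per SNP (Hardy–Weinberg), optional
  missingness completely at random.
* Cell compositions: Dirichlet with blood-like concentrations
  (granulocytes 10, CD4 T 4, CD8 T 2.5, B 1.5, NK 1.5, monocytes 1.5),
  giving realistic between-sample variation of the myeloid/lymphoid
  balance.
* Methylation: per probe, M = base + composition-weighted cell-type
  offsets + covariate effects + delta·dosage + N(0, noise_sd²), with
  noise_sd = 0.5 M-units by default; beta = 2^M / (2^M + 1). The
  cell-mixture term mixes per-cell-type logit offsets linearly on the M
  scale — the simplest structure a PCA surrogate can recover. Reference
  panel offsets are built from two latent contrasts (myeloid-vs-lymphoid
  and a monocyte axis, amplitude ~6 M-units) so the panel is genuinely
  low-rank, as a real discriminating panel is.
* Detection p-values: Beta(0.1, 100) for passing entries, Uniform(0, 1)
  for injected failures (rate 0.002) — only the filter threshold matters
  downstream.
* Annotation fixtures: non-overlapping toy genes with strand, per-tissue
  tilings of the chromosome into the seven collapsed chromatin-state
  categories, planted BEDPE anchor pairs, and enhancer intervals, all with
  ground-truth memberships recorded by direct position arithmetic,
  independent of the annotation engine they test.

What the generator does **not** emulate: probe type I/II design
differences, batch effects, spatial correlation of methylation along the
genome, LD between SNPs, and age–methylation interactions. Tests passing
on these simulations therefore establish the correctness and calibration
of the *statistics*, not robustness to array artefacts, which are the
business of upstream raw-intensity preprocessing (out of scope here).

# Genomic context and enrichment

Probes are classified against gene models as promoter (within 1500 bp of
a TSS and in no gene body), gene body, ambiguous (both), or intergenic —
a partition, asserted as such. Chromatin-state segmentations are consumed
per tissue, with state labels mapped to seven categories (enhancer, TSS,
transcription, quiescent, heterochromatin, Polycomb, ZNF/repeats) through
a user-supplied map — there is no canonical 18-state-to-7 table, so it is
config, not code. Coordinates follow BED semantics on disk (0-based
half-open) and 1-based inclusive positions in memory; the readers convert,
and boundary behaviour is covered by tests.

Enrichment of the associated CpG set uses Fisher's exact test
(two-sided, the conventional sum of table probabilities at or below the
observed one). The 2×2 table compares associated probes against the
tested-but-not-associated background by default: Fisher's test assumes
disjoint rows, while the visually natural "associated versus all tested"
comparison double-counts the associated set. The overlapping variant is
available behind `background = "all_tested"` for comparability, and no
claim is made about which convention any published figure used. Q-values
are computed per family: genomic region classes in one family, all
(tissue × category) chromatin tests pooled in another, enhancer sets in a
third.

Interaction counts per CpG (number of ChIA-PET anchor pairs covering it)
are compared between associated and background probes with a two-sided
Mann–Whitney U test with tie correction — the counts are heavily skewed,
so a rank test rather than a t test — switching to the exact permutation
distribution (complete enumeration) when the combined sample size is at
most 12, where the normal approximation is poorest.

# Power for replication designs

Replication power uses the noncentral-F formulation for testing one model
term: power = P(F′ > F_crit) with F′ ~ F(u, v, λ), λ = f2·(u + v + 1) and
f2 = R²/(1 − R²). The λ convention matches the classical f2 power
calculation; λ = f2·n is available behind a flag since both circulate,
and they differ noticeably at small v. At f2 = 0 the function returns the
significance level exactly (the identity, not a numerical quadrature).
The analytic values are checked against a 100,000-draw Monte-Carlo
regression oracle at three grid points.

# Numerical choices and degenerate inputs

* Beta values exactly 0 or 1 are clamped to [1e-6, 1 − 1e-6] before the
  logit — the array scale cannot produce exact 0/1 without rounding, and
  the clamp avoids infinite M values.
* If the reduced model already fits exactly (RSS ≈ 0 at machine
  precision), the LRT is defined as 0 and partial R² as 0: nothing is
  left for the genotype to explain. If the full model fits exactly, the
  statistic is infinite and p collapses to the smallest positive double,
  keeping p in (0, 1].
* PCA signs are fixed by making each component's largest-magnitude
  loading positive, so results are reproducible across LAPACK builds.
* Rank-deficient designs name the collinear columns instead of silently
  dropping them; constant dosages are an "untestable" status, not an
  error.
* `fisher.test` can return p marginally above 1 by rounding; enrichment
  clamps to the probability scale before q-value computation.

# Problem sizes used in the checks

The packaged checks simulate at the scale the pipeline targets: cohorts
of 350 samples for calibration (2000 null pairs), FDR (50 replicates of
50 pairs with 10 planted effects of 1.0 M-units), and parameter recovery
(100 replicates of a planted 0.5 M-unit effect); the full study-scale run
uses 355 samples, 52 SNPs and ~160 candidate probes per SNP, ~8400 tested
pairs. These sizes make the Monte-Carlo error of each property small
relative to its acceptance band while keeping a full run of the suite in
well under a minute per property.

# Known limitations

* The scan is cis-only and additive: no trans scanning, dominance,
  interactions, or mixed models for relatedness.
* Raw-intensity preprocessing (background correction, probe-design
  adjustment, batch correction) is upstream and out of scope; the package
  starts from beta values.
* The q-value smoother is noisy for small families (e.g. the 4-category
  genomic enrichment family); with few tests pi0 estimation has little to
  work with, and the BH-equivalent pi0 = 1 can be forced where
  conservatism is preferred.
* The weight-category trend coding (0/1/2) assumes an ordered linear
  effect; a factor coding would cost a df and is not provided.
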