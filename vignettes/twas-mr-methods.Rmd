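---
title: "Methods: gene-based association and Mendelian randomization on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-based association and Mendelian randomization on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasmr)
```

## What the package computes

`twasmr` implements the statistical chain that links germline variation to
disease through gene expression, and exercises it end to end on simulated
cohorts with known ground truth:

1. **Expression prediction models.** For each gene, cis variants (within
   1 Mb of the gene body, both sides inclusive) predict
   covariate-residualized expression. Three frameworks are fitted: a
   single-tissue elastic net; a cross-tissue fit with a lasso penalty on
   within-tissue weights plus a group-lasso penalty tying each variant's
   weights across tissues; and a similarity-weighted fit that stacks all
   tissues' samples with weights $\mathrm{sim}(\text{target}, t)^p$. The
   best model per gene is the one with the highest cross-validated
   correlation $r$ between out-of-fold predictions and observed expression;
   a gene is *imputable* when $r > 0.1$ and the correlation test gives
   $P < 0.05$.
2. **Summary-statistics TWAS.** With model weights $w_l$, GWAS z-scores
   $z_l$, panel dosage SDs $\sigma_l$ and LD correlations $\rho_{ll'}$,
   the gene-level association is
   $$z_g = \frac{\sum_l w_l \sigma_l z_l}{\sigma_g}, \qquad
     \sigma_g^2 = \sum_{l,l'} w_l w_{l'} \sigma_l \sigma_{l'} \rho_{ll'},$$
   with $P = 2\Phi(-|z_g|)$ and Benjamini–Hochberg adjustment at a stated
   family size. Gene-level odds ratios use
   $\beta_g = \sum_l w_l \sigma_l^2 \beta_l / \sigma_g^2$ and
   $SE_g = \beta_g / z_g$.
3. **Mendelian randomization.** Independent exposure-associated variants
   ($P < 5\times10^{-8}$, pairwise $r^2 < 0.01$ within 250 kb) are
   harmonized against the outcome and fed to four estimators: IVW,
   weighted median (WME), Egger regression, and a heterogeneity-penalized
   estimator that gives each instrument its own L1-shrunk direct-effect
   term alongside an unpenalized common slope. Estimation requires at
   least three instruments; with fewer the estimators refuse (a classed
   condition, never a silent `NA`). Gene-locus-restricted runs keep only
   instruments within 1 Mb of the gene body, boundaries inclusive.
4. **PheWAS.** One summary-statistics TWAS per phenotype in a
   phecode-labelled catalog, BH-adjusted within the scan.

## The synthetic-data generator

The generator is first-class, tested code; every downstream claim in the
test suite rests on it.

**Genotypes.** Haplotypes come from a latent Gaussian copula with AR(1)
within-block correlation, thresholded at the allele-frequency quantile and
summed to dosages in $\{0,1,2\}$. Thresholding attenuates correlation
(tetrachoric to phi), so for each block the latent correlation is
*calibrated* — by root-finding on the bivariate normal orthant
probability — such that adjacent genotypes hit the configured `ld_rho` on
the genotype scale. This keeps the LD target closed-form and exact in
expectation. One MAF is drawn per block (mixed frequencies inside a block
would cap the attainable correlation below the target). At
`ld_rho = 0.9` with blocks of five, the mean within-block $r^2$ is about
0.75.

**Two seeds.** `population_seed` fixes the *architecture* — allele
frequencies, allele labels, causal-variant sets, true eQTL weights,
direct-effect assignments — while `seed` drives individual-level sampling.
An expression reference panel and a GWAS cohort simulated with the same
`population_seed` but different `seed`s therefore share one biology, which
is precisely the assumption TWAS transfers weights across datasets under.

**Expression.** Each gene's causal cis weights are drawn jointly across
tissues from a zero-mean Gaussian whose correlation equals the
tissue-similarity matrix (identical tissues at similarity 1, independent
at 0). Expression is
$y_t = \sqrt{h^2}\,\tilde g_t + \sqrt{1-h^2}\,\varepsilon + C\gamma$ with
$\tilde g_t$ the standardized genetic value; heritability is defined
relative to covariate-residualized expression, since the covariate block
$C\gamma$ (sex plus two genotype-independent components) adds variance on
top of the unit-variance genetic + noise mix.

**Phenotypes.** Disease is logistic:
$\mathrm{logit}\,P(y{=}1) = \alpha + \beta_g \sum_j \tilde g_j +
\sum_l \delta_l x_l$, with $\alpha$ solved for the target prevalence. The
$\delta_l$ are direct (horizontally pleiotropic) variant effects on a
configurable fraction of the causal genes' cis variants — the invalid
instruments. A logistic model rather than a liability threshold keeps the
simulated effects on the same log-OR scale as the GWAS summary statistics.
Per-variant statistics use a vectorised score test by default (one-step
log-OR, $SE = V^{-1/2}$), with per-variant Wald logistic regression as an
option; quantitative phenotypes use simple linear regression.

**Instrument-level scenarios.** Estimator calibration does not need
100 000-person cohorts: `simulate_instruments()` draws true instrument
effects ($|\gamma| \sim U(0.2, 0.5)$, oriented exposure-increasing, the
convention of instrument tables) and adds sampling noise with
$SE = 0.01$ — the per-SNP scale of consortium GWAS with order $10^5$
samples, which is where the trait-trait MR in this design operates. The
weighted-median robustness regime uses *balanced* invalid instruments
(direct effects of magnitude $0.5 \pm 0.1$ with random sign); the
Egger-recovery regime uses *directional* effects
($\delta \sim N(0.1, 0.05^2)$ on every instrument, independent of
instrument strength, i.e. InSIDE holds). With one-sided directional
contamination the weighted median's intrinsic quantile shift is
$\Phi^{-1}\!\big(0.5/(1-f)\big)\,\sigma_{\text{ratio}}$ at invalid
fraction $f$; at $f = 0.4$ and this noise scale that is a few hundredths,
visibly nonzero but an order of magnitude below the IVW bias.

**What the generator does not emulate.** Realistic allele-frequency
spectra and LD decay (blocks are exchangeable, AR-structured, one
chromosome); population structure and relatedness (the simulated PCs are
genotype-independent, so residualizing them is honest but easy);
winner's-curse selection of instruments across traits; trans-eQTLs;
case-control ascertainment (sampling is prospective at the stated
prevalence). Green tests therefore certify the *statistical machinery* —
calibration, identities, robustness under the stated violation models —
not performance on any real cohort.

## Numerical and design choices

* **Penalty grids.** The elastic-net path uses 50 log-spaced values from
  $\lambda_{max}$ (the smallest penalty giving the all-zero model) down
  four orders of magnitude; folds are a seeded permutation shared across
  frameworks so cross-validated accuracies are comparable. The
  cross-tissue fit uses one $(\lambda_1, \lambda_2)$ pair — constant
  across folds — selected from a $4\times4$ grid of fractions of the
  data-driven anchor $\max_t |x_j^\top y_t|/n$.
* **Cross-tissue solver.** Block coordinate descent with the exact
  proximal update per variant (soft-threshold per tissue, then group
  shrinkage), which decreases the objective monotonically; convergence at
  max coefficient change $<10^{-7}$, cap 500 sweeps, non-convergence
  returns the best iterate with a warning flag.
* **Weight scale.** Model weights are reported per SD of dosage
  (genotypes are standardized before fitting); `summary_twas()` handles
  both this and the per-allele scale explicitly.
* **Hidden expression factors.** Data-driven hidden-factor covariates are
  represented by the top expression principal components (default 5)
  appended to the known covariates before residualization.
* **BH at a stated family size.** `bh_adjust(p, m_total)` implements
  step-up BH with `m_total` at least the number of supplied values. The
  pipeline labels significance at FDR < 0.10 with `m_total = 9952` by
  default — the family size of the full transcriptome-wide scan it
  emulates — treating the simulated gene panel as a window of that
  transcriptome; this is conservative for the window. Pure simulation
  studies that want nominal calibration pass `m_total = NULL`.
* **Harmonization.** Outcome effects are aligned to the exposure's effect
  alleles; swapped alleles flip the sign and complement the frequency;
  palindromic (A/T, C/G) variants with either frequency in (0.4, 0.6) are
  dropped as strand-unresolvable. The operation is idempotent.
* **Clumping.** Greedy by ascending P, ties broken by chromosome then
  position; the window is center-to-center, inclusive; empty input yields
  an empty result rather than an error.
* **Egger inference** uses multiplicative residual overdispersion floored
  at 1, with P-values and intervals on the t-distribution with
  $n_{IV} - 2$ degrees of freedom — the overdispersion is estimated from
  few instruments, and at typical instrument counts the normal
  approximation undercovers by a visible margin (about 93% instead of 95%
  at 15 instruments). The other estimators use the normal approximation.
* **WME uncertainty** is a parametric bootstrap (default 1000 replicates,
  seeded; minimum 100) over redrawn effect pairs.
* **Heterogeneity-penalized estimator.** Implemented as a weighted lasso
  over per-instrument intercept columns with `penalty.factor = 0` on the
  slope, penalty chosen by cross-validation, bootstrap CI. It is a
  faithful-in-spirit implementation of per-instrument heterogeneity
  modeling, not a port of any published code.
* **Oracle-identity regime.** The summary-statistics TWAS equals the
  individual-level regression z only to $O(z^3/n)$; the equivalence check
  runs at a top-hit scale ($z \approx 6$ at $n = 2000$, predicted
  expression explaining ~2% of trait variance), where the discrepancy is
  below 0.05. At implausibly strong effects ($z > 15$) the identity
  degrades by construction.

## Problem sizes

Simulated checks were sized to be decisive yet quick: cohorts of 1 500 to
8 000 individuals over 40 to 500 variants; 200 replicates for estimator
calibration; 20 replicates of the end-to-end null pipeline (2 000 samples,
20 genes each); 5 end-to-end causal-recovery runs at 8 000 samples. The
expression panel defaults to 305 samples, the size of a single-tissue
reference panel.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- run_config(scenario = "causal_gene", seed = 2)
out <- run_pipeline(cfg, out_dir = "pipeline_run")
dplyr::select(out$twas, gene_id, zscore, pvalue, fdr_adjusted_p, significant)
out$mr_gene           # three-estimator causal inference per significant gene
out$mr_bidirectional  # trait A <-> trait B, all-SNP / locus-restricted / excluded
out$phewas            # top gene against the phenotype catalog
```

## Known limitations

Single-chromosome, block-exchangeable LD; no trans effects, no
fine-mapping or colocalization downstream of the TWAS; no multivariable MR
or Steiger filtering; the locus-restriction logic assumes gene coordinates
are supplied correctly; and all calibration statements are with respect to
the generator's assumptions listed above.
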