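#' Preset simulation scenarios
#'
#' Named configurations covering the study designs the package is exercised
#' against:
#' * `"null"` — no gene affects the phenotype (global null; TWAS P-values
#'   should be uniform).
#' * `"causal_gene"` — one gene (the first) with strong cis heritability
#'   drives disease risk through its expression (vertical pleiotropy); its
#'   cis region spans four LD blocks so clumping can recover at least three
#'   independent instruments.
#' * `"directional_pleiotropy"` — on top of the causal gene, every cis
#'   variant of that gene carries a direct outcome effect with nonzero mean
#'   (for Egger-intercept recovery).
#' * `"balanced_20"` / `"balanced_40"` — 20% / 40% of the causal gene's cis
#'   variants carry balanced (zero-mean) direct effects (weighted-median
#'   robustness regimes).
#'
#' @param name Scenario name.
#' @param seed Seed.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A [sim_config()].
#' @export
sim_scenario <- function(name = c("null", "causal_gene",
                                  "directional_pleiotropy",
                                  "balanced_20", "balanced_40"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    null = list(gene_effect = 0, pleiotropy_fraction = 0),
    causal_gene = list(
      n_samples = 8000L, n_variants = 320L, n_genes = 16L,
      ld_block_size = 5L, heritability = 0.6, causal_fraction = 0.3,
      gene_effect = 0.5, causal_genes = 1L),
    directional_pleiotropy = list(
      n_samples = 8000L, n_variants = 320L, n_genes = 16L,
      ld_block_size = 5L, heritability = 0.6, causal_fraction = 0.3,
      gene_effect = 0.5, causal_genes = 1L,
      pleiotropy_fraction = 1, pleiotropy_mean = 0.1, pleiotropy_sd = 0.05),
    balanced_20 = list(
      n_samples = 8000L, n_variants = 320L, n_genes = 16L,
      ld_block_size = 5L, heritability = 0.6, causal_fraction = 0.3,
      gene_effect = 0.5, causal_genes = 1L,
      pleiotropy_fraction = 0.2, pleiotropy_mean = 0, pleiotropy_sd = 0.3),
    balanced_40 = list(
      n_samples = 8000L, n_variants = 320L, n_genes = 16L,
      ld_block_size = 5L, heritability = 0.6, causal_fraction = 0.3,
      gene_effect = 0.5, causal_genes = 1L,
      pleiotropy_fraction = 0.4, pleiotropy_mean = 0, pleiotropy_sd = 0.3)
  )
  do.call(sim_config, modifyList(base, c(list(seed = seed), list(...))))
}

#' Simulate an instrument set at the summary-statistics level
#'
#' Draws true instrument effects on the exposure, adds sampling noise at
#' consortium-GWAS scale, and generates outcome effects
#' \eqn{\beta_{out,j} = \theta\,\gamma_j + \alpha_j + noise}, where the
#' direct effects \eqn{\alpha_j} are nonzero for an `invalid_fraction` of
#' instruments and drawn from `N(direct_mean, direct_sd^2)` independently of
#' instrument strength (the InSIDE condition). With `balanced = TRUE` each
#' direct effect is additionally given a random sign, so the pleiotropy has
#' magnitude `direct_mean` but zero mean — the weighted-median robustness
#' regime; `balanced = FALSE` keeps all direct effects on one side
#' (directional pleiotropy, the Egger-intercept recovery design;
#' `invalid_fraction = 1` puts a direct effect on every instrument).
#'
#' @param n_iv Number of instruments.
#' @param true_effect Causal effect \eqn{\theta} (log-OR per exposure unit).
#' @param invalid_fraction Fraction of instruments with direct effects.
#' @param direct_mean,direct_sd Direct-effect distribution.
#' @param balanced Give each direct effect a random sign (zero-mean,
#'   balanced pleiotropy).
#' @param gamma_range Range of |true exposure effects| (drawn uniformly;
#'   log-OR scale typical of genome-wide significant loci in large GWAS).
#' @param se_exp,se_out Per-instrument standard errors (defaults of 0.01
#'   correspond to consortium GWAS of order 1e5 samples).
#' @param seed Seed.
#' @return An `instrument_set` tibble with a logical `invalid` column and
#'   the truth (`true_effect`, direct effects) in the `"truth"` attribute.
#' @examples
#' iv <- simulate_instruments(12, true_effect = 0.3, invalid_fraction = 0.4,
#'                            direct_mean = 0.5, seed = 3)
#' mr_weighted_median(iv, n_boot = 200, seed = 3)
#' @export
simulate_instruments <- function(n_iv = 15L, true_effect = 0.3,
                                 invalid_fraction = 0,
                                 direct_mean = 0.5, direct_sd = 0.1,
                                 balanced = FALSE,
                                 gamma_range = c(0.2, 0.5),
                                 se_exp = 0.01, se_out = 0.01,
                                 seed = 1L) {
  set.seed(seed)
  # effect alleles coded exposure-increasing (the instrument-table
  # convention), so directional pleiotropy stays directional
  gamma <- runif(n_iv, gamma_range[1], gamma_range[2])
  n_invalid <- round(invalid_fraction * n_iv)
  invalid <- seq_len(n_iv) %in% sample.int(n_iv, n_invalid)
  alpha <- ifelse(invalid, rnorm(n_iv, direct_mean, direct_sd), 0)
  if (balanced) alpha <- alpha * sample(c(-1, 1), n_iv, replace = TRUE)

  tbl <- tibble(
    variant_id = sprintf("iv%03d", seq_len(n_iv)),
    beta_exp = gamma + rnorm(n_iv, 0, se_exp),
    se_exp = se_exp,
    beta_out = true_effect * gamma + alpha + rnorm(n_iv, 0, se_out),
    se_out = se_out,
    invalid = invalid
  )
  out <- as_instrument_set(tbl, exposure_id = "simulated")
  attr(out, "truth") <- list(true_effect = true_effect, gamma = gamma,
                             direct_effects = alpha)
  out
}

#' Simulate a pair of trait GWAS with one-way causality
#'
#' Builds summary statistics for two traits over a shared set of independent
#' variants: trait A has its own instruments (nonzero SNP effects), trait B
#' has its own disjoint instruments plus — through the causal effect
#' `delta_ab` of A on B — an induced effect `delta_ab * gamma_A` at A's
#' instruments. B has no effect on A, so MR should detect A to B and return
#' null for B to A. The accompanying panel treats all variants as
#' independent (instrument SNPs after clumping).
#'
#' @param n_variants Total variants (instruments plus null filler).
#' @param n_inst_each Instruments per trait.
#' @param delta_ab Causal effect of A on B (log-OR per liability SD).
#' @param gamma_range Range of |instrument effects|.
#' @param se Per-variant GWAS standard error for both traits.
#' @param seed Seed.
#' @return A list: `gwas_a`, `gwas_b` (summary tibbles), `panel`
#'   ([ld_panel()] with identity LD), `truth` (instrument ids and
#'   `delta_ab`).
#' @export
simulate_gwas_pair <- function(n_variants = 200L, n_inst_each = 12L,
                               delta_ab = 0.3,
                               gamma_range = c(0.2, 0.5),
                               se = 0.01, seed = 1L) {
  set.seed(seed)
  stopifnot(2L * n_inst_each <= n_variants)
  variants <- tibble(
    variant_id = sprintf("v%05d", seq_len(n_variants)),
    chrom = "1",
    pos = seq_len(n_variants) * 1000000L,  # spaced beyond any clump window
    effect_allele = "A", other_allele = "G",
    eaf = runif(n_variants, 0.1, 0.5)
  )
  idx_a <- seq_len(n_inst_each)
  idx_b <- n_inst_each + seq_len(n_inst_each)
  gamma_a <- numeric(n_variants)
  gamma_b <- numeric(n_variants)
  gamma_a[idx_a] <- runif(n_inst_each, gamma_range[1], gamma_range[2]) *
    sample(c(-1, 1), n_inst_each, replace = TRUE)
  gamma_b[idx_b] <- runif(n_inst_each, gamma_range[1], gamma_range[2]) *
    sample(c(-1, 1), n_inst_each, replace = TRUE)
  true_a <- gamma_a                      # B does not cause A
  true_b <- gamma_b + delta_ab * gamma_a # A causes B

  mk <- function(truth) {
    variants |>
      mutate(beta = truth + rnorm(n_variants, 0, se), se = se,
             pvalue = z_to_p(.data$beta / se), n = 1e5,
             monomorphic = FALSE)
  }
  R <- diag(n_variants)
  dimnames(R) <- list(variants$variant_id, variants$variant_id)
  list(gwas_a = mk(true_a), gwas_b = mk(true_b),
       panel = ld_panel(R, variants),
       truth = list(instruments_a = variants$variant_id[idx_a],
                    instruments_b = variants$variant_id[idx_b],
                    delta_ab = delta_ab))
}
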