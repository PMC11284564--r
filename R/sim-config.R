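#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The generator emulates
#' the statistical structure of a TWAS + MR study: LD-blocked genotypes, a
#' multi-tissue expression panel with cis genetic regulation, case-control
#' phenotypes mediated by genetically determined expression, and the GWAS
#' summary statistics they produce. One seed fully determines every draw.
#'
#' @param n_samples Number of individuals.
#' @param n_variants Number of variants; partitioned into LD blocks of
#'   `ld_block_size` and into `n_genes` contiguous cis regions.
#' @param n_genes Number of genes; `n_variants` must be divisible by it.
#' @param maf_range Length-2 numeric in (0, 1): minor-allele frequencies are
#'   drawn uniformly in this range, one per LD block (variants within a block
#'   share a MAF so the within-block LD target is attainable in closed form).
#' @param ld_block_size Variants per LD block.
#' @param ld_rho Target genotype correlation of *adjacent* variants within a
#'   block, in \[0, 1). Correlation decays AR(1)-style with distance on the
#'   latent scale; across blocks it is ~0. The latent Gaussian-copula
#'   correlation is calibrated so that thresholded genotypes hit this target.
#' @param n_tissues Number of tissues in the expression panel.
#' @param heritability Cis heritability of expression (fraction of expression
#'   variance explained by the causal cis variants), in \[0, 1\].
#' @param causal_fraction Fraction of each gene's cis variants that are causal
#'   eQTLs, in (0, 1].
#' @param gene_effect Log-odds of disease per SD of genetically determined
#'   expression of each causal gene.
#' @param causal_genes Indices of genes whose expression affects the
#'   phenotype (default: gene 1 when `gene_effect != 0`, none otherwise).
#' @param pleiotropy_fraction Fraction of the causal genes' cis variants that
#'   carry a *direct* (horizontally pleiotropic) effect on the phenotype.
#' @param pleiotropy_mean,pleiotropy_sd Normal parameters (log-odds units) of
#'   those direct effects; a nonzero mean gives directional pleiotropy,
#'   mean zero gives balanced pleiotropy.
#' @param prevalence Target case fraction; the logistic intercept is solved to
#'   hit it.
#' @param bp_spacing Base pairs between consecutive variants (all on one
#'   chromosome).
#' @param seed Integer seed; fully determines the output.
#' @param population_seed Seed for *population-level* draws — block allele
#'   frequencies, allele labels, causal-variant sets, true eQTL weights,
#'   direct-effect assignments. Defaults to `seed`. Two cohorts simulated
#'   with the same `population_seed` but different `seed`s share the same
#'   genetic architecture while sampling independent individuals (an
#'   expression reference panel and a GWAS cohort drawn from one
#'   population).
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_samples = 500, n_variants = 40, n_genes = 4, seed = 1)
#' @export
sim_config <- function(n_samples = 2000,
                       n_variants = 200,
                       n_genes = 20,
                       maf_range = c(0.1, 0.5),
                       ld_block_size = 5,
                       ld_rho = 0.7,
                       n_tissues = 3,
                       heritability = 0.3,
                       causal_fraction = 0.2,
                       gene_effect = 0,
                       causal_genes = NULL,
                       pleiotropy_fraction = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0.1,
                       prevalence = 0.5,
                       bp_spacing = 5000L,
                       seed = 1L,
                       population_seed = NULL) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes), maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_rho = as.numeric(ld_rho),
    n_tissues = as.integer(n_tissues), heritability = as.numeric(heritability),
    causal_fraction = as.numeric(causal_fraction),
    gene_effect = as.numeric(gene_effect),
    causal_genes = if (is.null(causal_genes)) {
      if (gene_effect != 0) 1L else integer(0)
    } else as.integer(causal_genes),
    pleiotropy_fraction = as.numeric(pleiotropy_fraction),
    pleiotropy_mean = as.numeric(pleiotropy_mean),
    pleiotropy_sd = as.numeric(pleiotropy_sd),
    prevalence = as.numeric(prevalence),
    bp_spacing = as.integer(bp_spacing), seed = as.integer(seed),
    population_seed = as.integer(population_seed %||% seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 1L || cfg$n_variants < 1L) {
    abort("n_samples and n_variants must be positive.")
  }
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range >= 1) || cfg$maf_range[1] > cfg$maf_range[2]) {
    abort("maf_range must be an increasing pair of frequencies in (0, 1).")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) {
    abort("ld_rho must lie in [0, 1).")
  }
  if (cfg$heritability < 0 || cfg$heritability > 1) {
    abort("heritability must lie in [0, 1].")
  }
  if (cfg$causal_fraction <= 0 || cfg$causal_fraction > 1) {
    abort("causal_fraction must lie in (0, 1].")
  }
  if (cfg$pleiotropy_fraction < 0 || cfg$pleiotropy_fraction > 1) {
    abort("pleiotropy_fraction must lie in [0, 1].")
  }
  if (cfg$prevalence <= 0.05 || cfg$prevalence >= 0.95) {
    abort("prevalence must lie in (0.05, 0.95).")
  }
  if (cfg$n_variants %% cfg$n_genes != 0L) {
    abort("n_variants must be divisible by n_genes.")
  }
  if (!is.finite(cfg$gene_effect)) abort("gene_effect must be finite.")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples, %d variants (%d genes, LD blocks of %d, rho=%.2f)\n",
              x$n_samples, x$n_variants, x$n_genes, x$ld_block_size, x$ld_rho))
  cat(sprintf("  %d tissues, h2=%.2f, causal_fraction=%.2f\n",
              x$n_tissues, x$heritability, x$causal_fraction))
  cat(sprintf("  gene_effect=%.3f, pleiotropy: %.0f%% ~ N(%.2f, %.2f^2), seed=%d\n",
              x$gene_effect, 100 * x$pleiotropy_fraction, x$pleiotropy_mean,
              x$pleiotropy_sd, x$seed))
  invisible(x)
}
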