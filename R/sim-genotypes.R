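#' Simulate LD-blocked genotype dosages
#'
#' Draws two haplotypes per individual from a latent Gaussian copula with
#' AR(1) within-block correlation, thresholds each at the frequency quantile,
#' and sums them into `{0, 1, 2}` dosages. Thresholding a Gaussian attenuates
#' correlation (tetrachoric to phi), so the latent correlation is calibrated
#' per block — by root-finding on the bivariate normal orthant probability —
#' such that adjacent genotypes hit `ld_rho` on the *genotype* scale.
#' Variants in different blocks are independent.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genotypes` with elements
#'   * `dosages`: `n_samples` x `n_variants` integer matrix in `{0, 1, 2}`,
#'     with variant IDs as column names;
#'   * `variants`: tibble of variant metadata (`variant_id`, `chrom`, `pos`,
#'     `effect_allele`, `other_allele`, `eaf`, `block`), 1-based positions;
#'   * `config`: the configuration used.
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples = 200, n_variants = 20,
#'                                    n_genes = 2, seed = 7))
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(config) {
  cfg <- validate_sim_config(config)
  n <- cfg$n_samples
  m <- cfg$n_variants
  b <- min(cfg$ld_block_size, m)
  block_of <- ((seq_len(m) - 1L) %/% b) + 1L
  n_blocks <- max(block_of)

  # population-level draws: frequencies and allele labels
  set.seed(cfg$population_seed)
  block_maf <- runif(n_blocks, cfg$maf_range[1], cfg$maf_range[2])
  allele_pairs <- non_palindromic_pairs()
  pair_idx <- sample.int(nrow(allele_pairs), m, replace = TRUE)

  # cohort-level draws: haplotypes
  set.seed(cfg$seed)
  dos <- matrix(0L, n, m)
  for (k in seq_len(n_blocks)) {
    idx <- which(block_of == k)
    p <- block_maf[k]
    rho_lat <- calibrate_latent_rho(cfg$ld_rho, p)
    L <- chol_ar1(length(idx), rho_lat)
    thr <- qnorm(p)
    h1 <- (matrix(rnorm(n * length(idx)), n) %*% L) < thr
    h2 <- (matrix(rnorm(n * length(idx)), n) %*% L) < thr
    dos[, idx] <- h1 + h2
  }
  storage.mode(dos) <- "integer"

  variants <- tibble(
    variant_id = sprintf("v%05d", seq_len(m)),
    chrom = "1",
    pos = seq_len(m) * cfg$bp_spacing,
    effect_allele = allele_pairs[pair_idx, 1L],
    other_allele = allele_pairs[pair_idx, 2L],
    eaf = block_maf[block_of],
    block = block_of
  )
  colnames(dos) <- variants$variant_id
  structure(list(dosages = dos, variants = variants, config = cfg),
            class = "sim_genotypes")
}

# All ordered allele pairs that are not strand-ambiguous (A/T, C/G excluded),
# so harmonization in simulated pipelines never drops palindromic variants.
non_palindromic_pairs <- function() {
  nt <- c("A", "C", "G", "T")
  out <- expand.grid(effect = nt, other = nt, stringsAsFactors = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  keep <- out$effect != out$other & comp[out$effect] != out$other
  as.matrix(out[keep, , drop = FALSE])
}

# Upper-triangular Cholesky factor of an AR(1) correlation matrix.
chol_ar1 <- function(k, rho) {
  if (k == 1L) return(matrix(1, 1, 1))
  chol(rho ^ abs(outer(seq_len(k), seq_len(k), "-")))
}

# P(Z1 < a, Z2 < a) for standard bivariate normal with correlation rho.
binorm_lower <- function(a, rho) {
  if (rho >= 1) return(pnorm(a))
  if (rho == 0) return(pnorm(a)^2)
  s <- sqrt(1 - rho^2)
  integrate(function(z) dnorm(z) * pnorm((a - rho * z) / s),
            lower = -Inf, upper = a, rel.tol = 1e-10)$value
}

# Latent Gaussian correlation such that alleles thresholded at qnorm(p) have
# (phi) correlation `target`. Equal thresholds make any target in [0, 1)
# attainable: corr rises continuously from 0 (rho = 0) to 1 (rho -> 1).
calibrate_latent_rho <- function(target, p) {
  if (target <= 0) return(0)
  a <- qnorm(p)
  f <- function(rho) {
    (binorm_lower(a, rho) - p^2) / (p * (1 - p)) - target
  }
  uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-8)$root
}

#' @export
print.sim_genotypes <- function(x, ...) {
  cat(sprintf("<sim_genotypes> %d samples x %d variants (%d LD blocks)\n",
              nrow(x$dosages), ncol(x$dosages), max(x$variants$block)))
  invisible(x)
}
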