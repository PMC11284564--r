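#' Simulate a case-control phenotype mediated by gene expression
#'
#' Disease liability follows a logistic model,
#' \deqn{\mathrm{logit}\,P(y=1) = \alpha + \beta_g \sum_{j \in causal}
#'   \tilde g_j + \sum_{l \in invalid} \delta_l x_l,}
#' with \eqn{\tilde g_j} the standardized genetically determined expression of
#' causal gene \eqn{j}, \eqn{\beta_g} = `gene_effect` (log-odds per SD), and
#' optional *direct* variant effects \eqn{\delta_l} on a `pleiotropy_fraction`
#' of the causal genes' cis variants (the invalid instruments), drawn from
#' `N(pleiotropy_mean, pleiotropy_sd^2)`. The intercept \eqn{\alpha} is solved
#' so the expected case fraction equals `prevalence`.
#'
#' @param geno A [simulate_genotypes()] result.
#' @param expr A [simulate_expression()] result, or a samples x genes matrix
#'   of (standardized) genetic values.
#' @param config The [sim_config()].
#' @return A list of class `sim_phenotype`: `phenotype` (0/1 integer vector),
#'   `truth` (list: `gene_effect`, `causal_genes`, `invalid_iv_ids`,
#'   `direct_effects`, `alpha`), `config`.
#' @examples
#' cfg <- sim_config(n_samples = 400, n_variants = 40, n_genes = 4,
#'                   gene_effect = 0.5, seed = 3)
#' g <- simulate_genotypes(cfg)
#' ph <- simulate_case_control(g, simulate_expression(g, cfg), cfg)
#' mean(ph$phenotype)
#' @export
simulate_case_control <- function(geno, expr, config = geno$config) {
  cfg <- validate_sim_config(config)
  gvalue <- if (inherits(expr, "sim_expression")) expr$truth$genetic_value else expr

  n <- nrow(geno$dosages)
  eta <- rep(0, n)
  for (j in cfg$causal_genes) {
    eta <- eta + cfg$gene_effect * gvalue[, j]
  }

  # population-level draws: which variants are invalid IVs, their effects
  set.seed(cfg$population_seed + 2L)
  invalid_ids <- character(0)
  direct <- numeric(0)
  if (cfg$pleiotropy_fraction > 0 && length(cfg$causal_genes) > 0) {
    q <- cfg$n_variants %/% cfg$n_genes
    cis_all <- unlist(lapply(cfg$causal_genes,
                             function(j) ((j - 1L) * q + 1L):(j * q)))
    n_inv <- max(1L, round(cfg$pleiotropy_fraction * length(cis_all)))
    inv_idx <- sort(sample(cis_all, n_inv))
    invalid_ids <- geno$variants$variant_id[inv_idx]
    direct <- rnorm(n_inv, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    X <- scale_dosages(geno$dosages[, inv_idx, drop = FALSE])
    eta <- eta + as.vector(X %*% direct)
  }

  # cohort-level draw: disease status
  set.seed(cfg$seed + 2L)

  alpha <- uniroot(function(a) mean(plogis(a + eta)) - cfg$prevalence,
                   interval = c(-20, 20), tol = 1e-10)$root
  y <- rbinom(n, 1L, plogis(alpha + eta))
  if (all(y == 0L) || all(y == 1L)) {
    abort(sprintf(
      "Degenerate phenotype: all %s (prevalence target %.2f, n = %d). Increase n_samples or adjust effects.",
      if (all(y == 1L)) "cases" else "controls", cfg$prevalence, n))
  }

  structure(list(
    phenotype = y,
    truth = list(gene_effect = cfg$gene_effect,
                 causal_genes = cfg$causal_genes,
                 invalid_iv_ids = invalid_ids,
                 direct_effects = setNames(direct, invalid_ids),
                 alpha = alpha),
    config = cfg
  ), class = "sim_phenotype")
}

#' Per-variant GWAS summary statistics
#'
#' Marginal association of every variant with a phenotype. For binary
#' phenotypes the default is the vectorised score test (one-step log-odds
#' estimate `beta = U/V`, `se = 1/sqrt(V)` with score `U` and null information
#' `V`), with `method = "wald"` running a per-variant logistic regression
#' instead. Quantitative phenotypes use simple linear regression (vectorised),
#' with a two-sided t P-value. Monomorphic variants are kept, flagged, and
#' carry `NA` statistics — never silently dropped.
#'
#' @param geno A [simulate_genotypes()] result, or a dosage matrix with
#'   variant IDs as column names (then `variants` must be supplied).
#' @param phenotype A [simulate_case_control()] result, a 0/1 vector, or a
#'   numeric vector (quantitative).
#' @param method `"score"` (default, binary only) or `"wald"`.
#' @param variants Variant metadata tibble when `geno` is a bare matrix.
#' @return A tibble with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `eaf`, `n`,
#'   `monomorphic`. `beta` is the marginal (log-odds for binary) effect per
#'   effect-allele copy; `z = beta/se`.
#' @examples
#' cfg <- sim_config(n_samples = 300, n_variants = 20, n_genes = 2, seed = 4)
#' g <- simulate_genotypes(cfg)
#' ph <- simulate_case_control(g, simulate_expression(g, cfg), cfg)
#' make_gwas_summary(g, ph)
#' @export
make_gwas_summary <- function(geno, phenotype, method = c("score", "wald"),
                              variants = NULL) {
  method <- match.arg(method)
  if (inherits(geno, "sim_genotypes")) {
    dos <- geno$dosages
    variants <- geno$variants
  } else {
    dos <- geno
    if (is.null(variants)) abort("Supply `variants` metadata with a bare dosage matrix.")
  }
  y <- if (inherits(phenotype, "sim_phenotype")) phenotype$phenotype else phenotype
  if (length(y) != nrow(dos)) abort("phenotype length must match rows of dosages.")
  binary <- all(y %in% c(0, 1))

  n <- nrow(dos)
  mono <- apply(dos, 2L, function(x) length(unique(x)) == 1L)
  beta <- se <- pval <- rep(NA_real_, ncol(dos))
  poly <- which(!mono)

  if (length(poly) > 0) {
    if (binary && method == "score") {
      pbar <- mean(y)
      Xc <- sweep(dos[, poly, drop = FALSE], 2L, colMeans(dos[, poly, drop = FALSE]))
      U <- as.vector(crossprod(Xc, y - pbar))
      V <- pbar * (1 - pbar) * colSums(Xc^2)
      beta[poly] <- U / V
      se[poly] <- 1 / sqrt(V)
      pval[poly] <- 2 * pnorm(-abs(beta[poly] / se[poly]))
    } else if (binary) {
      for (j in poly) {
        fit <- glm(y ~ dos[, j], family = binomial())
        cf <- summary(fit)$coefficients
        beta[j] <- cf[2L, 1L]
        se[j] <- cf[2L, 2L]
        pval[j] <- cf[2L, 4L]
      }
    } else {
      Xs <- dos[, poly, drop = FALSE]
      xm <- colMeans(Xs)
      Sxx <- colSums(Xs^2) - n * xm^2
      yc <- y - mean(y)
      Sxy <- as.vector(crossprod(Xs, yc))
      Syy <- sum(yc^2)
      b <- Sxy / Sxx
      sigma2 <- pmax(Syy - b * Sxy, 0) / (n - 2L)
      beta[poly] <- b
      se[poly] <- sqrt(sigma2 / Sxx)
      tt <- b / se[poly]
      pval[poly] <- 2 * stats::pt(-abs(tt), df = n - 2L)
    }
  }

  variants |>
    select("variant_id", "chrom", "pos", "effect_allele", "other_allele") |>
    mutate(beta = beta, se = se, pvalue = pval,
           eaf = colMeans(dos) / 2, n = n, monomorphic = mono)
}
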