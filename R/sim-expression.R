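#' Simulate multi-tissue cis-regulated expression
#'
#' Partitions the simulated variants into `n_genes` contiguous cis regions,
#' picks `causal_fraction` of each gene's cis variants as causal eQTLs, and
#' draws their effect sizes jointly across tissues from a zero-mean Gaussian
#' whose cross-tissue correlation equals the supplied `similarity` matrix
#' (identical tissues for similarity 1, independent for 0). Expression is
#'
#' \deqn{y_t = \sqrt{h^2}\,\tilde g_t + \sqrt{1-h^2}\,\epsilon +
#'       C\,\gamma,}
#'
#' where \eqn{\tilde g_t} is the standardized genetic value (standardized
#' dosages times true weights), so the cis-genetic fraction of the
#' residualized expression variance is `heritability`. `C` holds the
#' simulated covariates (sex and two genotype-independent principal
#' components), mirroring the covariate structure expression panels are
#' residualized against.
#'
#' @param geno A [simulate_genotypes()] result.
#' @param config The [sim_config()] (usually `geno$config`).
#' @param similarity Optional `n_tissues` x `n_tissues` tissue-similarity
#'   matrix; symmetric, unit diagonal, entries in \[0, 1\]. Defaults to
#'   exchangeable 0.8 off-diagonal.
#' @return A list of class `sim_expression`:
#'   * `expression`: named list (one per tissue) of samples x genes matrices;
#'   * `genes`: tibble (`gene_id`, `chrom`, `gene_start`, `gene_end`,
#'     `cis_variants` list-column);
#'   * `covariates`: samples x 3 matrix (`sex`, `PC1`, `PC2`);
#'   * `truth`: list with `weights` (tibble `gene_id`, `tissue`,
#'     `variant_id`, `weight` on the standardized-dosage scale) and
#'     `genetic_value` (samples x genes matrix, standardized, target tissue =
#'     first tissue).
#' @examples
#' cfg <- sim_config(n_samples = 300, n_variants = 40, n_genes = 4, seed = 2)
#' expr <- simulate_expression(simulate_genotypes(cfg), cfg)
#' names(expr$expression)
#' @export
simulate_expression <- function(geno, config = geno$config, similarity = NULL) {
  cfg <- validate_sim_config(config)
  if (is.null(similarity)) {
    similarity <- matrix(0.8, cfg$n_tissues, cfg$n_tissues)
    diag(similarity) <- 1
  }
  check_similarity(similarity, cfg$n_tissues)

  n <- nrow(geno$dosages)
  m <- ncol(geno$dosages)
  q <- m %/% cfg$n_genes
  tissues <- paste0("tissue", seq_len(cfg$n_tissues))
  X <- scale_dosages(geno$dosages)
  sim_sqrt <- mat_sqrt_psd(similarity)
  n_causal <- max(1L, ceiling(cfg$causal_fraction * q))

  # population-level draws: causal sets, true weights, covariate loadings
  set.seed(cfg$population_seed + 1L)
  arch <- map(seq_len(cfg$n_genes), function(j) {
    cis <- ((j - 1L) * q + 1L):(j * q)
    causal <- sort(sample(cis, n_causal))
    # rows: causal variants; cols: tissues; cross-tissue corr = similarity
    W <- matrix(rnorm(n_causal * cfg$n_tissues), n_causal) %*% sim_sqrt
    colnames(W) <- tissues
    list(cis = cis, causal = causal, W = W, cov_gamma = rnorm(3L, 0, 0.2))
  })

  # cohort-level draws: covariates and expression noise
  set.seed(cfg$seed + 1L)
  covars <- cbind(sex = rbinom(n, 1L, 0.5),
                  PC1 = rnorm(n), PC2 = rnorm(n))

  expr <- lapply(tissues, function(t) matrix(0, n, cfg$n_genes,
                                             dimnames = list(NULL, gene_ids(cfg))))
  names(expr) <- tissues
  gvalue <- matrix(0, n, cfg$n_genes, dimnames = list(NULL, gene_ids(cfg)))
  weight_rows <- vector("list", cfg$n_genes)
  gene_meta <- vector("list", cfg$n_genes)

  for (j in seq_len(cfg$n_genes)) {
    cis <- arch[[j]]$cis
    causal <- arch[[j]]$causal
    W <- arch[[j]]$W
    noise <- rnorm(n)
    cov_gamma <- arch[[j]]$cov_gamma
    for (ti in seq_along(tissues)) {
      g <- X[, causal, drop = FALSE] %*% W[, ti]
      g_std <- standardize_vec(g)
      if (ti == 1L) gvalue[, j] <- g_std
      expr[[ti]][, j] <- sqrt(cfg$heritability) * g_std +
        sqrt(1 - cfg$heritability) * noise + covars %*% cov_gamma
    }
    weight_rows[[j]] <- tibble(
      gene_id = gene_ids(cfg)[j],
      tissue = rep(tissues, each = n_causal),
      variant_id = rep(geno$variants$variant_id[causal], cfg$n_tissues),
      weight = as.vector(W)
    )
    gene_meta[[j]] <- tibble(
      gene_id = gene_ids(cfg)[j], chrom = "1",
      gene_start = geno$variants$pos[cis[1L]],
      gene_end = geno$variants$pos[cis[q]],
      cis_variants = list(geno$variants$variant_id[cis])
    )
  }

  structure(list(
    expression = expr,
    genes = list_rbind(gene_meta),
    covariates = covars,
    truth = list(weights = list_rbind(weight_rows), genetic_value = gvalue),
    config = cfg
  ), class = "sim_expression")
}

gene_ids <- function(cfg) sprintf("gene%03d", seq_len(cfg$n_genes))

check_similarity <- function(similarity, n_tissues) {
  if (!is.matrix(similarity) || nrow(similarity) != n_tissues ||
      ncol(similarity) != n_tissues) {
    abort(sprintf("similarity must be a %d x %d matrix.", n_tissues, n_tissues))
  }
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    abort("similarity matrix must be symmetric.")
  }
  if (max(abs(diag(similarity) - 1)) > 1e-8) {
    abort("similarity matrix must have unit diagonal.")
  }
  if (any(similarity < 0) || any(similarity > 1 + 1e-12)) {
    abort("similarity entries must lie in [0, 1].")
  }
  invisible(similarity)
}

# Symmetric square root with eigenvalue clipping; tolerates the rank-1
# all-ones matrix (identical tissues).
mat_sqrt_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

standardize_vec <- function(x) {
  s <- sd(x)
  if (s < .Machine$double.eps) return(x - mean(x))
  (x - mean(x)) / s
}

# Column-standardize dosages; monomorphic columns become all-zero.
scale_dosages <- function(dos) {
  mu <- colMeans(dos)
  s <- apply(dos, 2L, sd)
  s[s < .Machine$double.eps] <- Inf
  sweep(sweep(dos, 2L, mu), 2L, s, "/")
}
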