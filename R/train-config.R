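#' Training configuration for expression prediction models
#'
#' @param cis_window_bp Cis window: variants within this many base pairs of
#'   the gene body (both sides, inclusive) are candidate predictors. Default
#'   1 Mb.
#' @param n_folds Cross-validation folds (default 5); fold assignment is a
#'   seeded permutation of samples, shared across frameworks so their
#'   cross-validated accuracies are comparable.
#' @param alpha_mixing Elastic-net mixing parameter in (0, 1\] (default 0.5;
#'   1 = lasso).
#' @param n_lambda,lambda_min_ratio Penalty grid: `n_lambda` log-spaced
#'   values from the smallest lambda giving the all-zero model down by a
#'   factor `lambda_min_ratio` (default 50 values over 4 orders of
#'   magnitude).
#' @param lambda1_grid,lambda2_grid Within-tissue (lasso) and cross-tissue
#'   (group-lasso) penalty grids for the cross-tissue fit, as *fractions* of
#'   the data-driven maximum penalty; `NULL` uses
#'   `c(0.5, 0.2, 0.1, 0.05)` for both.
#' @param similarity_power_grid Exponents applied to tissue-similarity
#'   sample weights in the similarity-weighted fit (candidate values,
#'   selected by cross-validation in the target tissue).
#' @param max_iter,tol Coordinate-descent iteration cap and convergence
#'   tolerance (max absolute coefficient change) for the cross-tissue fit.
#' @param seed Seed controlling fold assignment.
#' @return A list of class `training_config`.
#' @export
training_config <- function(cis_window_bp = 1e6,
                            n_folds = 5L,
                            alpha_mixing = 0.5,
                            n_lambda = 50L,
                            lambda_min_ratio = 1e-4,
                            lambda1_grid = NULL,
                            lambda2_grid = NULL,
                            similarity_power_grid = c(0, 1, 2, 4, 8, 16),
                            max_iter = 500L,
                            tol = 1e-7,
                            seed = 1L) {
  if (n_folds < 2L) abort("n_folds must be at least 2.")
  if (alpha_mixing <= 0 || alpha_mixing > 1) {
    abort("alpha_mixing must lie in (0, 1].")
  }
  if (!is.null(lambda1_grid) && any(lambda1_grid < 0)) abort("penalties must be >= 0")
  if (!is.null(lambda2_grid) && any(lambda2_grid < 0)) abort("penalties must be >= 0")
  structure(list(
    cis_window_bp = cis_window_bp, n_folds = as.integer(n_folds),
    alpha_mixing = alpha_mixing, n_lambda = as.integer(n_lambda),
    lambda_min_ratio = lambda_min_ratio,
    lambda1_grid = lambda1_grid %||% c(0.5, 0.2, 0.1, 0.05),
    lambda2_grid = lambda2_grid %||% c(0.5, 0.2, 0.1, 0.05),
    similarity_power_grid = similarity_power_grid,
    max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed)
  ), class = "training_config")
}

# Seeded fold assignment; a permutation of 1..n cut into n_folds blocks.
make_folds <- function(n, n_folds, seed) {
  set.seed(seed)
  fold <- rep(seq_len(n_folds), length.out = n)
  sample(fold)
}

# Candidate cis variants: within cis_window_bp of the gene body, inclusive.
cis_variant_ids <- function(variants, gene, cis_window_bp) {
  variants |>
    filter(.data$chrom == gene$chrom,
           .data$pos >= gene$gene_start - cis_window_bp,
           .data$pos <= gene$gene_end + cis_window_bp) |>
    pull("variant_id")
}

# Pearson correlation of out-of-fold predictions vs observed, with the
# t-test P-value; degenerate predictions give r = 0, p = 1.
cv_performance <- function(pred, obs) {
  if (sd(pred) < .Machine$double.eps || sd(obs) < .Machine$double.eps) {
    return(list(cv_r = 0, cv_p = 1))
  }
  r <- cor(pred, obs)
  n <- length(obs)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(cv_r = r, cv_p = 2 * stats::pt(-abs(tt), df = n - 2))
}

new_expr_model <- function(gene, tissue, framework, weights, cv_r, cv_p,
                           extra = list()) {
  structure(c(list(
    gene_id = gene$gene_id, chrom = gene$chrom,
    gene_start = gene$gene_start, gene_end = gene$gene_end,
    tissue = tissue, framework = framework, weights = weights,
    cv_r = cv_r, cv_p = cv_p,
    imputable = is.finite(cv_r) && cv_r > 0.1 && cv_p < 0.05
  ), extra), class = "expr_model")
}

#' @export
print.expr_model <- function(x, ...) {
  cat(sprintf("<expr_model> %s [%s, %s]: %d nonzero weights, cv_r = %.3f (P = %.2g)%s\n",
              x$gene_id, x$tissue, x$framework,
              sum(x$weights$weight != 0), x$cv_r, x$cv_p,
              if (x$imputable) ", imputable" else ""))
  invisible(x)
}
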