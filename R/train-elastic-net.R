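#' Train a single-tissue elastic-net expression model
#'
#' Fits predicted expression as a sparse linear function of standardized cis
#' dosages by elastic net,
#' \deqn{\min_\beta \frac{1}{2n}\|y - X\beta\|^2 +
#'   \lambda\big[\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2/2\big],}
#' with the penalty chosen by k-fold cross-validation over a log-spaced grid
#' from \eqn{\lambda_{max}} (smallest penalty giving the all-zero model) down
#' four orders of magnitude. Cross-validated accuracy (`cv_r`, `cv_p`) is the
#' Pearson correlation between out-of-fold predictions and observed
#' expression and its two-sided t-test; a model whose out-of-fold predictions
#' are constant records `cv_r = 0` and is flagged non-imputable rather than
#' erroring. Reported weights are on the standardized-dosage scale.
#'
#' @param y Residualized expression vector for one gene.
#' @param dosages Samples x variants dosage matrix (variant IDs as column
#'   names).
#' @param variants Variant metadata tibble.
#' @param gene List or one-row tibble with `gene_id`, `chrom`, `gene_start`,
#'   `gene_end`.
#' @param config A [training_config()].
#' @param tissue Tissue label recorded in the model.
#' @return An `expr_model` object; `weights` is a tibble (`variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `weight`) of nonzero
#'   weights, all within the cis window.
#' @examples
#' cfg <- sim_config(n_samples = 300, n_variants = 20, n_genes = 2,
#'                   heritability = 0.5, seed = 9)
#' g <- simulate_genotypes(cfg)
#' ex <- simulate_expression(g, cfg)
#' y <- regress_out_covariates(ex$expression$tissue1, ex$covariates)[, 1]
#' train_elastic_net(y, g$dosages, g$variants, ex$genes[1, ])
#' @export
train_elastic_net <- function(y, dosages, variants, gene,
                              config = training_config(),
                              tissue = "tissue1") {
  gene <- as.list(gene)
  n <- length(y)
  if (n < 2L * config$n_folds) {
    abort("Need at least 2 * n_folds samples to train.")
  }
  cis_ids <- cis_variant_ids(variants, gene, config$cis_window_bp)
  if (length(cis_ids) == 0) abort("No cis variants for this gene.")
  X <- scale_dosages(dosages[, cis_ids, drop = FALSE])
  yc <- y - mean(y)

  lambda <- lambda_grid(X, yc, config)
  folds <- make_folds(n, config$n_folds, config$seed)
  oof <- matrix(NA_real_, n, length(lambda))
  for (k in seq_len(config$n_folds)) {
    test <- folds == k
    fit <- glmnet_fit(X[!test, , drop = FALSE], yc[!test],
                      alpha = config$alpha_mixing, lambda = lambda)
    oof[test, ] <- predict_glmnet(fit, X[test, , drop = FALSE], lambda)
  }
  cv_mse <- colMeans((oof - yc)^2)
  best <- which.min(cv_mse)
  perf <- cv_performance(oof[, best], yc)

  fit_full <- glmnet_fit(X, yc, alpha = config$alpha_mixing, lambda = lambda)
  w <- coef_at(fit_full, lambda, best)
  weights <- weight_table(w, cis_ids, variants)

  new_expr_model(gene, tissue, "elastic_net", weights,
                 perf$cv_r, perf$cv_p,
                 extra = list(lambda = lambda[best], n_samples = n))
}

# Log-spaced penalty grid anchored at the null-model lambda.
lambda_grid <- function(X, yc, config) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, yc))) / (n * config$alpha_mixing)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$n_lambda))
}

# glmnet on pre-standardized predictors; pads single-column designs with an
# all-zero dummy (glmnet needs >= 2 columns; a zero column never enters).
glmnet_fit <- function(X, yc, alpha, lambda) {
  padded <- ncol(X) < 2L
  if (padded) X <- cbind(X, `.dummy.` = 0)
  fit <- glmnet::glmnet(X, yc, alpha = alpha, lambda = lambda,
                        standardize = FALSE, intercept = TRUE)
  attr(fit, "padded") <- padded
  fit
}

predict_glmnet <- function(fit, Xnew, lambda) {
  if (isTRUE(attr(fit, "padded"))) Xnew <- cbind(Xnew, `.dummy.` = 0)
  as.matrix(predict(fit, newx = Xnew, s = lambda, exact = FALSE))
}

coef_at <- function(fit, lambda, idx) {
  cf <- as.matrix(coef(fit, s = lambda[idx]))[-1L, 1L]
  if (isTRUE(attr(fit, "padded"))) cf <- cf[names(cf) != ".dummy."]
  cf
}

weight_table <- function(w, ids, variants) {
  tibble(variant_id = ids, weight = unname(w[ids])) |>
    filter(.data$weight != 0) |>
    left_join(select(variants, "variant_id", "chrom", "pos",
                     "effect_allele", "other_allele"),
              by = "variant_id") |>
    select("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "weight")
}
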