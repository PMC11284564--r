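#' Train a similarity-weighted joint-tissue expression model
#'
#' Borrows strength across tissues for a target tissue by stacking every
#' tissue's samples and fitting a *weighted* elastic net in which the sample
#' weight of a tissue-\eqn{t} observation is
#' \eqn{\mathrm{sim}(\mathrm{target}, t)^p}. The exponent \eqn{p} is chosen
#' from `similarity_power_grid` jointly with the penalty by cross-validation
#' evaluated **only in the target tissue**, and folds are split by donor so
#' no donor contributes to both the training and test side of a fold (a
#' donor's samples in other tissues would otherwise leak). Samples from
#' zero-similarity tissues carry weight 0 and are excluded from the fit.
#'
#' @param y_list Named list of residualized expression vectors (one per
#'   tissue, same donors in the same order; use `NA` entries for donors
#'   missing from a tissue).
#' @param dosages,variants,gene,config As in [train_elastic_net()].
#' @param similarity Tissue-similarity matrix (symmetric, unit diagonal,
#'   entries in \[0, 1\]) with dimnames matching `names(y_list)`.
#' @param target Target tissue name (default first tissue).
#' @return An `expr_model` (framework `"similarity_weighted"`) for the
#'   target tissue, with the selected exponent in `$power`.
#' @examples
#' cfg <- sim_config(n_samples = 250, n_variants = 10, n_genes = 1,
#'                   n_tissues = 2, heritability = 0.5, seed = 11)
#' g <- simulate_genotypes(cfg)
#' ex <- simulate_expression(g, cfg)
#' ys <- lapply(ex$expression, function(m)
#'   regress_out_covariates(m, ex$covariates)[, 1])
#' sim <- matrix(c(1, .8, .8, 1), 2, dimnames = list(names(ys), names(ys)))
#' train_similarity_weighted(ys, g$dosages, g$variants, ex$genes[1, ], sim)
#' @export
train_similarity_weighted <- function(y_list, dosages, variants, gene,
                                      similarity,
                                      config = training_config(),
                                      target = names(y_list)[1]) {
  gene <- as.list(gene)
  tissues <- names(y_list)
  check_similarity(similarity, length(tissues))
  if (is.null(dimnames(similarity))) {
    dimnames(similarity) <- list(tissues, tissues)
  }
  if (!target %in% tissues) abort("target must be one of the supplied tissues.")

  n <- length(y_list[[1]])
  cis_ids <- cis_variant_ids(variants, gene, config$cis_window_bp)
  if (length(cis_ids) == 0) abort("No cis variants for this gene.")
  X <- scale_dosages(dosages[, cis_ids, drop = FALSE])

  # long format: one row per (donor, tissue) with observed expression
  long <- list_rbind(map(tissues, function(t) {
    keep <- which(!is.na(y_list[[t]]))
    tibble(donor = keep, tissue = t,
           y = y_list[[t]][keep] - mean(y_list[[t]][keep]),
           sim = similarity[target, t])
  }))

  folds <- make_folds(n, config$n_folds, config$seed)  # donor-level folds
  target_rows <- long$tissue == target
  y_target <- long$y[target_rows]
  donor_target <- long$donor[target_rows]

  best <- list(err = Inf)
  pow_weights <- function(sim, p) ifelse(sim == 0, 0, sim^p)  # 0^0 stays 0
  for (p in config$similarity_power_grid) {
    wts <- pow_weights(long$sim, p)
    use <- wts > 0
    lam <- lambda_grid(X[long$donor[use], , drop = FALSE], long$y[use], config)
    oof <- matrix(NA_real_, length(y_target), length(lam))
    for (k in seq_len(config$n_folds)) {
      tr <- use & folds[long$donor] != k
      te <- which(folds[donor_target] == k)
      if (sum(tr) < 2L || length(te) == 0L) next
      fit <- glmnet_weighted(X[long$donor[tr], , drop = FALSE], long$y[tr],
                             wts[tr], config$alpha_mixing, lam)
      oof[te, ] <- predict_glmnet(fit, X[donor_target[te], , drop = FALSE], lam)
    }
    cv_mse <- colMeans((oof - y_target)^2)
    idx <- which.min(cv_mse)
    if (length(idx) == 1 && cv_mse[idx] < best$err) {
      best <- list(err = cv_mse[idx], power = p, lambda = lam, idx = idx,
                   oof = oof[, idx])
    }
  }

  perf <- cv_performance(best$oof, y_target)
  wts <- pow_weights(long$sim, best$power)
  use <- wts > 0
  fit_full <- glmnet_weighted(X[long$donor[use], , drop = FALSE], long$y[use],
                              wts[use], config$alpha_mixing, best$lambda)
  w <- coef_at(fit_full, best$lambda, best$idx)
  new_expr_model(gene, target, "similarity_weighted",
                 weight_table(w, cis_ids, variants),
                 perf$cv_r, perf$cv_p,
                 extra = list(power = best$power,
                              lambda = best$lambda[best$idx],
                              n_samples = length(y_target)))
}

glmnet_weighted <- function(X, y, w, alpha, lambda) {
  padded <- ncol(X) < 2L
  if (padded) X <- cbind(X, `.dummy.` = 0)
  fit <- glmnet::glmnet(X, y, weights = w, alpha = alpha, lambda = lambda,
                        standardize = FALSE, intercept = TRUE)
  attr(fit, "padded") <- padded
  fit
}
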