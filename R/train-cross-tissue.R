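#' Train cross-tissue expression models (sparse-group penalty)
#'
#' Joint fit across tissues with a lasso penalty on individual within-tissue
#' weights and a group-lasso penalty tying each variant's weights across
#' tissues:
#' \deqn{\min_B \sum_t \frac{1}{2 n_t}\|y_t - X\beta_t\|^2 +
#'   \lambda_1 \sum_{j,t} |\beta_{jt}| + \lambda_2 \sum_j \|\beta_{j\cdot}\|_2.}
#' The group term encourages a variant to be selected in all tissues or none.
#' Solved by block coordinate descent: with standardized predictors the
#' per-variant block update is the exact proximal step (soft-threshold each
#' tissue's partial correlation by \eqn{\lambda_1}, then shrink the block's
#' Euclidean norm by \eqn{\lambda_2}), which decreases the objective
#' monotonically. One `(lambda1, lambda2)` pair — the same in every
#' cross-validation fold — is chosen from the grid by total out-of-fold MSE
#' across tissues.
#'
#' @param y_list Named list (one per tissue) of residualized expression
#'   vectors for one gene; tissues share the sample set.
#' @param dosages,variants,gene,config As in [train_elastic_net()].
#' @return A named list of `expr_model` objects (framework
#'   `"cross_tissue_group"`), one per tissue, each with its own out-of-fold
#'   `cv_r`/`cv_p`; the attribute `"converged"` on each model records
#'   whether coordinate descent met the tolerance (a warning is raised
#'   otherwise and the best iterate is returned).
#' @examples
#' cfg <- sim_config(n_samples = 250, n_variants = 10, n_genes = 1,
#'                   n_tissues = 2, heritability = 0.5, seed = 10)
#' g <- simulate_genotypes(cfg)
#' ex <- simulate_expression(g, cfg)
#' ys <- lapply(ex$expression, function(m)
#'   regress_out_covariates(m, ex$covariates)[, 1])
#' models <- train_cross_tissue(ys, g$dosages, g$variants, ex$genes[1, ])
#' @export
train_cross_tissue <- function(y_list, dosages, variants, gene,
                               config = training_config()) {
  gene <- as.list(gene)
  tissues <- names(y_list) %||% paste0("tissue", seq_along(y_list))
  names(y_list) <- tissues
  n <- length(y_list[[1]])
  if (any(lengths(y_list) != n)) abort("All tissues must share the sample set.")

  cis_ids <- cis_variant_ids(variants, gene, config$cis_window_bp)
  if (length(cis_ids) == 0) abort("No cis variants for this gene.")
  X <- scale_dosages(dosages[, cis_ids, drop = FALSE])
  Y <- vapply(y_list, function(y) y - mean(y), numeric(n))

  # data-driven penalty anchors: largest |x'y|/n over tissues
  anchor <- max(abs(crossprod(X, Y))) / n
  grid <- expand.grid(lambda1 = anchor * config$lambda1_grid,
                      lambda2 = anchor * config$lambda2_grid)

  folds <- make_folds(n, config$n_folds, config$seed)
  cv_err <- numeric(nrow(grid))
  oof_store <- vector("list", nrow(grid))
  for (g_i in seq_len(nrow(grid))) {
    oof <- matrix(NA_real_, n, length(tissues))
    for (k in seq_len(config$n_folds)) {
      test <- folds == k
      fit <- sparse_group_descent(X[!test, , drop = FALSE],
                                  Y[!test, , drop = FALSE],
                                  grid$lambda1[g_i], grid$lambda2[g_i],
                                  config$max_iter, config$tol)
      oof[test, ] <- X[test, , drop = FALSE] %*% fit$beta
    }
    cv_err[g_i] <- mean((oof - Y)^2)
    oof_store[[g_i]] <- oof
  }
  best <- which.min(cv_err)
  fit_full <- sparse_group_descent(X, Y, grid$lambda1[best],
                                   grid$lambda2[best],
                                   config$max_iter, config$tol)
  if (!fit_full$converged) {
    warn(sprintf("Cross-tissue fit for %s did not converge in %d iterations; returning best iterate.",
                 gene$gene_id, config$max_iter))
  }

  out <- lapply(seq_along(tissues), function(ti) {
    perf <- cv_performance(oof_store[[best]][, ti], Y[, ti])
    m <- new_expr_model(gene, tissues[ti], "cross_tissue_group",
                        weight_table(setNames(fit_full$beta[, ti], cis_ids),
                                     cis_ids, variants),
                        perf$cv_r, perf$cv_p,
                        extra = list(lambda1 = grid$lambda1[best],
                                     lambda2 = grid$lambda2[best],
                                     n_samples = n))
    attr(m, "converged") <- fit_full$converged
    m
  })
  names(out) <- tissues
  out
}

# Block coordinate descent for the multi-tissue sparse-group objective.
# X: n x p (columns centered); Y: n x T centered. The per-variant block
# subproblem is (v_j/2)||beta_{j.} - g/v_j||^2 + lambda1 l1 + lambda2 l2
# with curvature v_j = x_j'x_j/n and gradient anchor
# g_t = x_j' res_t / n + v_j beta_{jt}; its exact minimizer is the prox
# (soft-threshold by lambda1/v_j, then group-shrink by lambda2/v_j), so
# every sweep decreases the objective monotonically.
sparse_group_descent <- function(X, Y, lambda1, lambda2, max_iter, tol) {
  n <- nrow(X)
  p <- ncol(X)
  Tn <- ncol(Y)
  beta <- matrix(0, p, Tn)
  res <- Y
  v <- colSums(X^2) / n
  active <- which(v > .Machine$double.eps)  # monomorphic columns stay at zero
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in active) {
      b_old <- beta[j, ]
      u <- crossprod(X[, j], res)[1, ] / n + v[j] * b_old
      s <- sign(u) * pmax(abs(u) - lambda1, 0) / v[j]
      nrm <- sqrt(sum(s^2))
      b_new <- if (nrm > 0) s * max(0, 1 - (lambda2 / v[j]) / nrm) else s * 0
      db <- b_new - b_old
      if (any(db != 0)) {
        res <- res - X[, j] %*% t(db)
        beta[j, ] <- b_new
        delta <- max(delta, max(abs(db)))
      }
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged)
}

# Objective value, exposed for descent-property checks.
sparse_group_objective <- function(X, Y, beta, lambda1, lambda2) {
  n <- nrow(X)
  res <- Y - X %*% beta
  sum(colSums(res^2)) / (2 * n) + lambda1 * sum(abs(beta)) +
    lambda2 * sum(sqrt(rowSums(beta^2)))
}
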