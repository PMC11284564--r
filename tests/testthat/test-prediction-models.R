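test_that("covariate residualization is an exact orthogonal projection", {
  set.seed(31)
  n <- 200
  covar <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5), pc = rnorm(n))
  Y <- matrix(rnorm(n * 4), n)

  # zero covariates: centering
  cen <- regress_out_covariates(Y, NULL)
  expect_equal(colMeans(cen), rep(0, 4), tolerance = 1e-12)
  expect_equal(cen, sweep(Y, 2, colMeans(Y)))

  # exact linear function of covariates: residuals vanish
  Ylin <- cbind(1, covar) %*% matrix(rnorm(16), 4)
  expect_lt(max(abs(regress_out_covariates(Ylin, covar))), 1e-8)

  # residuals orthogonal to every covariate column
  res <- regress_out_covariates(Y, covar)
  expect_lt(max(abs(cor(res, covar))), 1e-8)

  # rank deficiency names the collinear column
  covar_bad <- cbind(covar, dup = covar[, "age"])
  expect_error(regress_out_covariates(Y, covar_bad), "dup")
})

test_that("elastic net recovers a strong single eQTL", {
  cfg <- sim_config(n_samples = 300, n_variants = 20, n_genes = 2, seed = 32)
  g <- simulate_genotypes(cfg)
  Xs <- scale(g$dosages)
  set.seed(3200)
  y <- Xs[, 5] + rnorm(300, 0, 0.1)
  m <- train_elastic_net(y, g$dosages, g$variants, list(
    gene_id = "toy", chrom = "1", gene_start = 1, gene_end = 100000))
  expect_gt(m$cv_r, 0.9)
  expect_true(m$imputable)
  expect_true("v00005" %in% m$weights$variant_id)
  expect_gt(abs(m$weights$weight[m$weights$variant_id == "v00005"]), 0.5)
})

test_that("elastic net is calibrated under the null", {
  # pure-noise expression across genes and seeds: few imputable calls
  flags <- unlist(lapply(1:2, function(s) {
    cfg <- sim_config(n_samples = 300, n_variants = 100, n_genes = 20,
                      seed = 100 + s)
    g <- simulate_genotypes(cfg)
    set.seed(s)
    sapply(seq_len(20), function(j) {
      y <- rnorm(300)
      m <- train_elastic_net(y, g$dosages, g$variants,
                             as.list(list(gene_id = sprintf("g%d", j),
                                          chrom = "1",
                                          gene_start = (j - 1) * 25000 + 1,
                                          gene_end = j * 25000)))
      m$imputable
    })
  }))
  expect_lte(mean(flags), 0.10)
})

test_that("a duplicated predictor splits the weight of the original", {
  cfg <- sim_config(n_samples = 400, n_variants = 20, n_genes = 2, seed = 33)
  g <- simulate_genotypes(cfg)
  set.seed(3300)
  y <- scale(g$dosages)[, 5] + rnorm(400, 0, 0.3)
  gene <- list(gene_id = "toy", chrom = "1", gene_start = 1, gene_end = 100000)
  m_single <- train_elastic_net(y, g$dosages, g$variants, gene)

  dup <- cbind(g$dosages, v_dup = g$dosages[, 5])
  vdup <- dplyr::bind_rows(g$variants,
                           dplyr::mutate(g$variants[5, ], variant_id = "v_dup"))
  m_dup <- train_elastic_net(y, dup, vdup, gene)
  w1 <- m_single$weights$weight[m_single$weights$variant_id == "v00005"]
  w2 <- sum(m_dup$weights$weight[m_dup$weights$variant_id %in%
                                   c("v00005", "v_dup")])
  expect_equal(w2, w1, tolerance = 0.05)
})

test_that("cross-tissue fit with lambda2 = 0 reduces to the lasso", {
  cfg <- sim_config(n_samples = 250, n_variants = 10, n_genes = 1,
                    n_tissues = 1, heritability = 0.5, seed = 34)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  y <- regress_out_covariates(ex$expression$tissue1, ex$covariates)[, 1]
  gene <- as.list(ex$genes[1, c("gene_id", "chrom", "gene_start", "gene_end")])

  # same single penalty for both solvers
  X <- twasmr:::scale_dosages(g$dosages)
  yc <- y - mean(y)
  lam <- 0.05
  fit_glmnet <- glmnet::glmnet(X, yc, alpha = 1, lambda = lam,
                               standardize = FALSE, intercept = TRUE)
  w_glmnet <- as.numeric(coef(fit_glmnet))[-1]
  fit_cd <- twasmr:::sparse_group_descent(X, matrix(yc), lam, 0, 500, 1e-9)
  expect_lt(max(abs(fit_cd$beta[, 1] - w_glmnet)), 1e-4)
})

test_that("the group penalty selects a shared eQTL in both tissues or neither", {
  # 5-SNP toy with one eQTL shared by two tissues
  set.seed(35)
  n <- 200
  X <- scale(matrix(rbinom(n * 5, 2, 0.3), n))
  y1 <- X[, 3] * 0.8 + rnorm(n, 0, 0.5)
  y2 <- X[, 3] * 0.8 + rnorm(n, 0, 0.5)
  Y <- cbind(y1 - mean(y1), y2 - mean(y2))
  for (lam2 in c(0.05, 0.2, 0.5, 1.5)) {
    fit <- twasmr:::sparse_group_descent(X, Y, 0.01, lam2, 500, 1e-9)
    sel <- fit$beta[3, ] != 0
    expect_true(all(sel) || !any(sel))
  }
  # verify the returned solution beats grid perturbations of the objective
  fit <- twasmr:::sparse_group_descent(X, Y, 0.05, 0.2, 500, 1e-9)
  obj0 <- twasmr:::sparse_group_objective(X, Y, fit$beta, 0.05, 0.2)
  set.seed(36)
  for (i in 1:20) {
    pert <- fit$beta + matrix(rnorm(10, 0, 0.02), 5)
    expect_gte(twasmr:::sparse_group_objective(X, Y, pert, 0.05, 0.2), obj0)
  }
})

test_that("coordinate descent decreases the objective monotonically", {
  set.seed(37)
  n <- 150
  X <- scale(matrix(rnorm(n * 8), n))
  Y <- scale(matrix(rnorm(n * 3), n), scale = FALSE)
  lam1 <- 0.05; lam2 <- 0.1
  objs <- sapply(1:6, function(it)
    twasmr:::sparse_group_objective(
      X, Y, twasmr:::sparse_group_descent(X, Y, lam1, lam2, it, 0)$beta,
      lam1, lam2))
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("similarity-weighted training reduces to the elastic net for identity similarity", {
  cfg <- sim_config(n_samples = 250, n_variants = 10, n_genes = 1,
                    n_tissues = 2, heritability = 0.5, seed = 38)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  ys <- lapply(ex$expression, function(m)
    regress_out_covariates(m, ex$covariates)[, 1])
  gene <- ex$genes[1, ]
  id_sim <- diag(2)
  dimnames(id_sim) <- list(names(ys), names(ys))
  jt <- train_similarity_weighted(ys, g$dosages, g$variants, gene, id_sim,
                                  target = "tissue1")
  en <- train_elastic_net(ys$tissue1, g$dosages, g$variants, gene)
  w_of <- function(w, ids) {
    v <- setNames(w$weight, w$variant_id)[ids]
    v[is.na(v)] <- 0
    unname(v)
  }
  all_ids <- union(jt$weights$variant_id, en$weights$variant_id)
  expect_lt(max(abs(w_of(jt$weights, all_ids) - w_of(en$weights, all_ids))),
            1e-4)
  expect_equal(jt$cv_r, en$cv_r, tolerance = 1e-6)
})

test_that("borrowing strength from an identical tissue improves accuracy", {
  gains <- sapply(1:5, function(s) {
    cfg <- sim_config(n_samples = 300, n_variants = 10, n_genes = 1,
                      n_tissues = 2, heritability = 0.4, seed = 200 + s)
    g <- simulate_genotypes(cfg)
    ex <- simulate_expression(g, cfg,
                              similarity = matrix(1, 2, 2))
    ys <- lapply(ex$expression, function(m)
      regress_out_covariates(m, ex$covariates)[, 1])
    # target tissue observed for only half the donors
    ys$tissue1[151:300] <- NA
    gene <- ex$genes[1, ]
    sim1 <- matrix(1, 2, 2)
    dimnames(sim1) <- list(names(ys), names(ys))
    jt <- train_similarity_weighted(ys, g$dosages, g$variants, gene, sim1,
                                    target = "tissue1")
    en <- train_elastic_net(ys$tissue1[1:150], g$dosages[1:150, ],
                            g$variants, gene)
    jt$cv_r - en$cv_r
  })
  expect_gt(median(gains), 0)
})

test_that("best-model selection honors performance, imputability, tie-breaks", {
  mk <- function(cv_r, cv_p, fw) {
    twasmr:::new_expr_model(
      list(gene_id = "g", chrom = "1", gene_start = 1, gene_end = 10),
      "tissue1", fw,
      tibble::tibble(variant_id = "v1", chrom = "1", pos = 5,
                     effect_allele = "A", other_allele = "G", weight = 1),
      cv_r, cv_p)
  }
  cands <- list(mk(0.05, 0.01, "elastic_net"),
                mk(0.3, 0.01, "cross_tissue_group"),
                mk(0.2, 0.01, "similarity_weighted"))
  expect_equal(select_best_model(cands)$cv_r, 0.3)

  # sub-threshold best accuracy: not imputable
  expect_null(select_best_model(list(mk(0.09, 0.001, "elastic_net"))))
  # significant but weak correlation is still not imputable
  expect_null(select_best_model(list(mk(0.3, 0.2, "elastic_net"))))

  tie <- list(mk(0.3, 0.01, "similarity_weighted"),
              mk(0.3, 0.01, "elastic_net"))
  expect_equal(select_best_model(tie)$framework, "elastic_net")
})

test_that("weight tables round-trip through the interchange format", {
  cfg <- tiny_config(seed = 39)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  y <- regress_out_covariates(ex$expression$tissue1, ex$covariates)[, 1]
  m <- train_elastic_net(y, g$dosages, g$variants, ex$genes[1, ])
  tbl <- weights_table(list(m))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  back <- models_from_weights(readr::read_tsv(path, show_col_types = FALSE))
  expect_equal(back[[1]]$weights$weight, m$weights$weight, tolerance = 1e-9)
  expect_equal(back[[1]]$cv_r, m$cv_r, tolerance = 1e-9)
  expect_equal(back[[1]]$gene_id, m$gene_id)
  expect_equal(back[[1]]$imputable, m$imputable)
})
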