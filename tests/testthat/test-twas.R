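test_that("z_to_p matches published TWAS table values", {
  # printed Z-scores and P-values for three susceptibility genes
  expect_equal(z_to_p(-6.940), 3.92e-12, tolerance = 0.005)
  expect_equal(z_to_p(5.675), 1.39e-08, tolerance = 0.005)
  expect_equal(z_to_p(3.844), 1.21e-04, tolerance = 0.005)
  expect_equal(z_to_p(0), 1)
})

test_that("z_to_p is strictly decreasing and stable far into the tail", {
  z <- seq(0, 40, by = 0.5)
  lp <- z_to_log10p(z)
  expect_true(all(diff(lp) < 0))
  expect_true(all(is.finite(lp)))
  expect_equal(z_to_log10p(40), log10(2) + pnorm(-40, log.p = TRUE) / log(10))
  expect_error(z_to_p(Inf))
})

test_that("bh_adjust agrees with a brute-force step-up oracle", {
  brute <- function(p, m) {
    o <- order(p)
    n <- length(p)
    adj <- sapply(seq_len(n), function(i)
      min(1, min(p[o][i:n] * m / (i:n))))
    out <- numeric(n)
    out[o] <- adj
    out
  }
  set.seed(50)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))
    expect_equal(bh_adjust(p), brute(p, length(p)), tolerance = 1e-12)
    m_tot <- length(p) + sample(0:100, 1)
    expect_equal(bh_adjust(p, m_tot), brute(p, m_tot), tolerance = 1e-12)
  }
  # ordinary BH case cross-checked against stats::p.adjust
  p <- runif(20)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(bh_adjust(0.5, 1), 0.5)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(runif(5), m_total = 3), "m_total")
})

test_that("bh_adjust output is rank-monotone and order-invariant", {
  set.seed(51)
  p <- runif(30)
  adj <- bh_adjust(p, m_total = 100)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
  shuf <- sample(30)
  expect_equal(bh_adjust(p[shuf], 100), adj[shuf])
})

test_that("or_ci_from_beta_z reproduces published confidence intervals", {
  abo <- or_ci_from_beta_z(1.147, 5.653)
  expect_equal(abo$ci_low, 1.094, tolerance = 0.005)
  expect_equal(abo$ci_high, 1.203, tolerance = 0.005)
  prc1 <- or_ci_from_beta_z(7.389, 3.879)
  expect_equal(prc1$ci_low, 2.690, tolerance = 0.005)
  expect_equal(prc1$ci_high, 20.302, tolerance = 0.005)
  expect_warning(deg <- or_ci_from_beta_z(1, 2), "degenerate")
  expect_equal(deg$ci_low, 1)
  expect_equal(deg$ci_high, 1)
  expect_error(or_ci_from_beta_z(1.2, 0), "undefined")
})

test_that("a single-variant model reduces to that variant's z", {
  stats <- sumstats_row("v1", beta = 0.25, se = 0.05)
  panel <- cor_panel(diag(1))
  m <- twasmr:::new_expr_model(
    list(gene_id = "g", chrom = "1", gene_start = 900, gene_end = 1100),
    "tissue1", "elastic_net",
    tibble::tibble(variant_id = "v1", chrom = "1", pos = 1000,
                   effect_allele = "A", other_allele = "G", weight = 1),
    0.5, 1e-5)
  r <- summary_twas(m, stats, panel)
  expect_equal(r$zscore, 0.25 / 0.05, tolerance = 1e-12)
  expect_equal(r$pvalue, z_to_p(5))

  # weight sign equivariance
  m_neg <- m
  m_neg$weights$weight <- -1
  expect_equal(summary_twas(m_neg, stats, panel)$zscore, -r$zscore)
})

test_that("swapped GWAS alleles flip the variant's contribution", {
  stats <- sumstats_row("v1", effect_allele = "G", other_allele = "A",
                        beta = 0.25, se = 0.05)
  panel <- cor_panel(diag(1))
  m <- twasmr:::new_expr_model(
    list(gene_id = "g", chrom = "1", gene_start = 900, gene_end = 1100),
    "tissue1", "elastic_net",
    tibble::tibble(variant_id = "v1", chrom = "1", pos = 1000,
                   effect_allele = "A", other_allele = "G", weight = 1),
    0.5, 1e-5)
  expect_equal(summary_twas(m, stats, panel)$zscore, -5, tolerance = 1e-12)
})

test_that("genes with no testable variant are skipped with a reason", {
  stats <- sumstats_row("v9", pos = 99999)
  panel <- cor_panel(diag(1))
  m <- twasmr:::new_expr_model(
    list(gene_id = "g", chrom = "1", gene_start = 900, gene_end = 1100),
    "tissue1", "elastic_net",
    tibble::tibble(variant_id = "v1", chrom = "1", pos = 1000,
                   effect_allele = "A", other_allele = "G", weight = 1),
    0.5, 1e-5)
  expect_error(summary_twas(m, stats, panel), class = "twasmr_no_overlap")
  scan <- twas_scan(list(m), stats, panel)
  expect_equal(nrow(scan), 0)
  expect_equal(attr(scan, "skipped")$gene_id, "g")
})

test_that("summary TWAS matches the individual-level oracle across genes", {
  cfg <- sim_config(n_samples = 2000, n_variants = 100, n_genes = 10,
                    heritability = 0.5, seed = 52)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  set.seed(5200)  # distinct stream from the generator seeds
  y <- 0.15 * ex$truth$genetic_value[, 1] + rnorm(cfg$n_samples)
  ss <- make_gwas_summary(g, y)
  panel <- ld_panel(g)
  Xs <- scale(g$dosages)
  for (j in seq_len(10)) {
    m <- truth_model(ex, g, j)
    r <- summary_twas(m, ss, panel)
    pred <- Xs[, m$weights$variant_id, drop = FALSE] %*% m$weights$weight
    t_ind <- summary(lm(y ~ pred))$coefficients[2, 3]
    expect_lt(abs(r$zscore - t_ind), 0.05)
  }
})

test_that("twas_scan applies BH across the scan and orders by P", {
  cfg <- sim_config(n_samples = 1000, n_variants = 60, n_genes = 6,
                    heritability = 0.5, seed = 53)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  set.seed(5300)  # distinct stream from the generator seeds
  y <- 0.3 * ex$truth$genetic_value[, 2] + rnorm(1000)
  ss <- make_gwas_summary(g, y)
  panel <- ld_panel(g)
  models <- lapply(1:6, function(j) truth_model(ex, g, j))
  scan <- twas_scan(models, ss, panel, m_total = 9952)
  expect_equal(scan$gene_id[1], "gene002")
  expect_true(all(diff(scan$pvalue) >= 0))
  expect_equal(scan$fdr_adjusted_p, bh_adjust(scan$pvalue, 9952))
  expect_true(all(scan$fdr_adjusted_p >= scan$pvalue))
})
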