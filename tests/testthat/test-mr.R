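test_that("Wald ratios follow their closed form and exclusion rule", {
  iv <- as_instrument_set(tibble::tibble(
    beta_exp = c(0.1, 0.2, 0), se_exp = 0.01,
    beta_out = c(0.2, 0.1, 0.5), se_out = 0.05))
  r <- mr_wald_ratios(iv)
  expect_equal(r$ratio, c(2, 0.5))
  expect_equal(r$ratio_se, c(0.5, 0.25))
  expect_equal(attr(r, "excluded")$reason, "zero exposure effect")

  # proportional effects: all ratios equal the constant
  ivp <- as_instrument_set(tibble::tibble(
    beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
    beta_out = 0.7 * c(0.1, 0.2, 0.3), se_out = 0.05))
  expect_equal(mr_wald_ratios(ivp)$ratio, rep(0.7, 3))
})

test_that("IVW equals the weighted mean of ratios and the simple mean for equal SEs", {
  # equal exposure effects and outcome SEs: simple mean of ratios
  iv_eq <- as_instrument_set(tibble::tibble(
    beta_exp = rep(0.2, 4), se_exp = 0.01,
    beta_out = c(0.02, 0.04, 0.06, 0.08), se_out = 0.05))
  est <- mr_ivw(iv_eq)
  expect_equal(est$estimate, mean(c(0.02, 0.04, 0.06, 0.08) / 0.2),
               tolerance = 1e-12)

  # two IVs (plus a zero-weight third), hand-computed weighted mean
  iv2 <- as_instrument_set(tibble::tibble(
    beta_exp = c(0.2, 0.4, 0.3), se_exp = 0.01,
    beta_out = c(0.06, 0.2, 0.09), se_out = c(0.05, 0.1, 0.05)))
  w <- iv2$beta_exp^2 / iv2$se_out^2
  manual <- sum(w * iv2$beta_out / iv2$beta_exp) / sum(w)
  est2 <- mr_ivw(iv2)
  expect_equal(est2$estimate, manual, tolerance = 1e-12)
  expect_equal(est2$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(est2$pvalue, z_to_p(est2$estimate / est2$se))
})

test_that("the weighted median interpolates correctly", {
  # equal weights, ratios (1, 2, 3, 10, 11): plain median 3
  iv <- as_instrument_set(tibble::tibble(
    beta_exp = rep(1, 5), se_exp = 0.01,
    beta_out = c(1, 2, 3, 10, 11), se_out = 1))
  est <- mr_weighted_median(iv, n_boot = 100, seed = 1)
  expect_equal(est$estimate, 3)

  # all ratios equal: estimate is that constant with small SE
  ivc <- as_instrument_set(tibble::tibble(
    beta_exp = c(0.2, 0.3, 0.4), se_exp = 1e-4,
    beta_out = 0.5 * c(0.2, 0.3, 0.4), se_out = 1e-4))
  estc <- mr_weighted_median(ivc, n_boot = 200, seed = 2)
  expect_equal(estc$estimate, 0.5, tolerance = 1e-3)
  expect_lt(estc$se, 0.01)

  expect_error(mr_weighted_median(iv, n_boot = 50), "at least 100")
})

test_that("weighted median tolerates <50% invalid weight and degrades beyond", {
  est_at <- function(frac, seeds) {
    sapply(seeds, function(s) mr_weighted_median(
      simulate_instruments(15, true_effect = 0.3, invalid_fraction = frac,
                           direct_mean = 0.5, direct_sd = 0.1,
                           balanced = TRUE, seed = s),
      n_boot = 100, seed = s)$estimate)
  }
  below <- est_at(0.4, 1:40)
  above <- est_at(0.8, 1:40)
  expect_lt(abs(mean(below) - 0.3), 0.05)
  expect_gt(abs(mean(above) - 0.3), abs(mean(below) - 0.3))
})

test_that("Egger regression recovers slope and directional intercept", {
  # three exactly collinear points: slope/intercept exact
  iv <- as_instrument_set(tibble::tibble(
    beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
    beta_out = 0.05 + 0.4 * c(0.1, 0.2, 0.3), se_out = 0.02))
  e <- suppressWarnings(mr_egger(iv))
  expect_equal(e$estimate, 0.4, tolerance = 1e-10)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)

  # constant direct effect on every instrument
  iv2 <- simulate_instruments(20, true_effect = 0.3, invalid_fraction = 1,
                              direct_mean = 0.1, direct_sd = 0, seed = 7)
  e2 <- mr_egger(iv2)
  expect_lt(abs(e2$intercept - 0.1), 0.02)
  expect_lt(abs(e2$estimate - 0.3), 0.05)

  # no pleiotropy: intercept test is calibrated (coverage near 95%)
  cover <- sapply(1:60, function(s) {
    ivn <- simulate_instruments(15, true_effect = 0.3, invalid_fraction = 0,
                                seed = s)
    en <- mr_egger(ivn)
    abs(en$intercept) <= qt(0.975, df = en$df) * en$intercept_se
  })
  expect_gte(mean(cover), 0.85)
})

test_that("the heterogeneity-penalized estimator shrinks to IVW and resists outliers", {
  iv <- simulate_instruments(12, true_effect = 0.3, invalid_fraction = 0,
                             seed = 11)
  h <- mr_het_penalized(iv, seed = 11, n_boot = 100)
  expect_equal(h$estimate, mr_ivw(iv)$estimate, tolerance = 0.02)

  # one strong outlier: its heterogeneity term activates and the estimate
  # stays closer to truth than IVW
  iv_out <- iv
  iv_out$beta_out[1] <- iv_out$beta_out[1] + 0.6
  h_out <- mr_het_penalized(iv_out, seed = 11, n_boot = 100)
  expect_gte(h_out$n_het_nonzero, 1)
  expect_lt(abs(h_out$estimate - 0.3), abs(mr_ivw(iv_out)$estimate - 0.3))
})

test_that("no estimator emits an estimate with fewer than three instruments", {
  iv2 <- as_instrument_set(tibble::tibble(
    beta_exp = c(0.2, 0.3), se_exp = 0.01,
    beta_out = c(0.06, 0.09), se_out = 0.05))
  expect_error(mr_ivw(iv2), class = "mr_refusal")
  expect_error(mr_weighted_median(iv2, n_boot = 100), class = "mr_refusal")
  expect_error(mr_egger(iv2), class = "mr_refusal")
  expect_error(mr_het_penalized(iv2), class = "mr_refusal")
  expect_error(mr_all_methods(iv2), class = "mr_refusal")
})

test_that("estimators are equivariant under exposure sign recoding", {
  iv <- simulate_instruments(10, true_effect = 0.25, invalid_fraction = 0.2,
                             direct_mean = 0.3, balanced = TRUE, seed = 13)
  flipped <- iv
  flipped$beta_exp <- -flipped$beta_exp
  flipped$beta_out <- -flipped$beta_out
  expect_equal(mr_ivw(flipped)$estimate, mr_ivw(iv)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(flipped, 200, seed = 3)$estimate,
               mr_weighted_median(iv, 200, seed = 3)$estimate,
               tolerance = 1e-10)
  expect_equal(mr_egger(flipped)$estimate, mr_egger(iv)$estimate,
               tolerance = 1e-10)
})

test_that("identical ratios collapse IVW, WME and Egger onto one value", {
  be <- c(0.15, 0.25, 0.35, 0.45)
  iv <- as_instrument_set(tibble::tibble(
    beta_exp = be, se_exp = 1e-6, beta_out = 0.6 * be, se_out = 0.01))
  expect_equal(mr_ivw(iv)$estimate, 0.6, tolerance = 1e-9)
  expect_equal(mr_weighted_median(iv, 100, seed = 1)$estimate, 0.6,
               tolerance = 1e-9)
  expect_equal(suppressWarnings(mr_egger(iv))$estimate, 0.6, tolerance = 1e-6)
})

test_that("locus restriction applies the 1 Mb boundary inclusively", {
  stats_exp <- dplyr::bind_rows(
    sumstats_row("v1", pos = 1000200, beta = 0.5, se = 0.05, pvalue = 1e-20),
    sumstats_row("v2", pos = 1000201, beta = 0.5, se = 0.05, pvalue = 1e-20))
  stats_out <- dplyr::mutate(stats_exp, beta = 0.1)
  panel <- cor_panel(diag(2), pos = c(1000200, 1000201))
  iv <- build_instruments(stats_exp, stats_out, panel,
                          locus = list(chrom = "1", gene_start = 100,
                                       gene_end = 200),
                          locus_window_bp = 1e6)
  expect_equal(iv$variant_id, "v1")  # 1,000,200 in; 1,000,201 out
})

test_that("instrument building refuses nothing but estimation enforces the minimum", {
  pair <- simulate_gwas_pair(n_variants = 60, n_inst_each = 2, seed = 3)
  iv <- build_instruments(pair$gwas_a, pair$gwas_b, pair$panel)
  expect_lte(nrow(iv), 2)
  expect_error(mr_all_methods(iv), class = "mr_refusal")
})

test_that("a null exposure yields no instruments at genome-wide threshold", {
  set.seed(19)
  m <- 500
  variants <- tibble::tibble(
    variant_id = sprintf("v%03d", 1:m), chrom = "1", pos = (1:m) * 1e6,
    effect_allele = "A", other_allele = "G", eaf = 0.3)
  null_stats <- variants |>
    dplyr::mutate(beta = rnorm(m, 0, 0.01), se = 0.01,
                  pvalue = z_to_p(beta / se), n = 1e5, monomorphic = FALSE)
  R <- diag(m)
  dimnames(R) <- list(variants$variant_id, variants$variant_id)
  kept <- ld_clump(null_stats, ld_panel(R, variants))
  expect_equal(nrow(kept), 0)
})
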