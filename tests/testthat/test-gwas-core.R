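test_that("summary statistics round-trip losslessly through TSV", {
  cfg <- sim_config(n_samples = 400, n_variants = 1000, n_genes = 100,
                    seed = 21)
  g <- simulate_genotypes(cfg)
  ph <- simulate_case_control(g, simulate_expression(g, cfg), cfg)
  ss <- make_gwas_summary(g, ph)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path)
  expect_equal(nrow(back), nrow(ss))
  expect_identical(back$variant_id, ss$variant_id)  # row order preserved
  for (col in c("beta", "se", "pvalue", "eaf")) {
    rel <- abs(back[[col]] - ss[[col]]) / pmax(abs(ss[[col]]), 1e-300)
    expect_lt(max(rel, na.rm = TRUE), 1e-6)
  }
})

test_that("invalid rows are rejected with line numbers, valid rows kept", {
  tbl <- dplyr::bind_rows(
    sumstats_row("v1", pos = 100),
    sumstats_row("v2", pos = 200, se = 0),
    sumstats_row("v3", pos = 300))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  expect_warning(out <- read_summary_stats(path), "rejected")
  expect_equal(out$variant_id, c("v1", "v3"))
  rej <- attr(out, "rejected")
  expect_equal(rej$variant_id, "v2")
  expect_equal(rej$line, 3L)  # file line including header
  expect_match(rej$reason, "se")
})

test_that("a missing required column is an error", {
  tbl <- dplyr::select(sumstats_row("v1"), -"se")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  expect_error(suppressWarnings(read_summary_stats(path)),
               "missing required column")
})

test_that("fixed-effect meta-analysis matches closed forms", {
  s1 <- sumstats_row("v1", beta = 0.2, se = 0.1)
  # single study: identity
  m1 <- meta_fixed_effect(list(s1))
  expect_equal(m1$beta, 0.2)
  expect_equal(m1$se, 0.1)

  # k identical studies: same beta, se shrinks by sqrt(k)
  for (k in c(2, 4)) {
    mk <- meta_fixed_effect(rep(list(s1), k))
    expect_equal(mk$beta, 0.2, tolerance = 1e-12)
    expect_equal(mk$se, 0.1 / sqrt(k), tolerance = 1e-12)
  }

  # hand-computed weighted mean: weights 100 and 25
  s2 <- sumstats_row("v1", beta = 0.1, se = 0.1)
  s3 <- sumstats_row("v1", beta = 0.3, se = 0.2)
  m <- meta_fixed_effect(list(s2, s3))
  expect_equal(m$beta, 0.14, tolerance = 1e-10)
  expect_equal(m$se, 0.08944272, tolerance = 1e-6)
})

test_that("meta-analysis is order-invariant and never inflates the SE", {
  set.seed(42)
  studies <- lapply(1:4, function(i)
    sumstats_row("v1", beta = rnorm(1, 0.1, 0.05), se = runif(1, 0.05, 0.3)))
  m_fwd <- meta_fixed_effect(studies)
  m_rev <- meta_fixed_effect(rev(studies))
  expect_equal(m_fwd$beta, m_rev$beta)
  expect_equal(m_fwd$se, m_rev$se)
  expect_lte(m_fwd$se, min(sapply(studies, function(s) s$se)))
})

test_that("meta-analysis refuses unharmonized alleles and empty input", {
  s1 <- sumstats_row("v1")
  s2 <- sumstats_row("v1", effect_allele = "G", other_allele = "A")
  expect_error(meta_fixed_effect(list(s1, s2)), "Unharmonized")
  expect_error(meta_fixed_effect(list()), "At least one")
})

test_that("harmonization aligns, flips, drops ambiguous palindromes", {
  exp <- sumstats_row("v1", effect_allele = "A", other_allele = "G",
                      beta = 0.2, eaf = 0.3)
  # identical orientation: untouched
  same <- harmonize_effects(exp, exp)
  expect_equal(same$beta_out, 0.2)
  expect_equal(same$eaf_out, 0.3)

  # swapped alleles: sign flip + frequency complement
  out_sw <- sumstats_row("v1", effect_allele = "G", other_allele = "A",
                         beta = 0.3, eaf = 0.7)
  sw <- harmonize_effects(exp, out_sw)
  expect_equal(sw$beta_out, -0.3)
  expect_equal(sw$eaf_out, 0.3)
  expect_equal(sw$effect_allele, "A")

  # ambiguous palindrome dropped with reason
  exp_at <- sumstats_row("v2", pos = 200, effect_allele = "A",
                         other_allele = "T", eaf = 0.5)
  h <- harmonize_effects(exp_at, exp_at)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "dropped")$reason, "palindromic-ambiguous")

  # non-ambiguous palindrome is kept
  exp_at2 <- sumstats_row("v2", pos = 200, effect_allele = "A",
                          other_allele = "T", eaf = 0.1)
  expect_equal(nrow(harmonize_effects(exp_at2, exp_at2)), 1)

  # incompatible allele sets excluded with reason code
  out_bad <- sumstats_row("v1", effect_allele = "A", other_allele = "C")
  hb <- harmonize_effects(exp, out_bad)
  expect_equal(nrow(hb), 0)
  expect_equal(attr(hb, "dropped")$reason, "incompatible-alleles")
})

test_that("harmonizing an already-aligned pair is a no-op", {
  exp <- sumstats_row("v1", beta = 0.2)
  out <- sumstats_row("v1", effect_allele = "G", other_allele = "A",
                      beta = 0.3, eaf = 0.7)
  once <- harmonize_effects(exp, out)
  realigned <- dplyr::mutate(exp,
                             beta = once$beta_out, se = once$se_out,
                             pvalue = once$pvalue_out, eaf = once$eaf_out)
  twice <- harmonize_effects(exp, realigned)
  expect_equal(twice$beta_out, once$beta_out)
  expect_equal(twice$eaf_out, once$eaf_out)
})
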