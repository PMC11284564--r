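#' Two-sided P-value from a z-score
#'
#' \eqn{P = 2\Phi(-|z|)}, evaluated through the lower tail so no
#' \eqn{1-\Phi} cancellation occurs; [z_to_log10p()] returns
#' \eqn{\log_{10} P} computed on the log scale, finite far beyond where the
#' P-value itself underflows double precision.
#'
#' @param z Numeric vector of z-scores.
#' @return P-values in (0, 1\].
#' @examples
#' z_to_p(-6.940)   # 3.92e-12
#' z_to_log10p(40)  # about -349
#' @export
z_to_p <- function(z) {
  stopifnot(all(is.finite(z)))
  2 * pnorm(-abs(z))
}

#' @rdname z_to_p
#' @export
z_to_log10p <- function(z) {
  stopifnot(all(is.finite(z)))
  (log(2) + pnorm(-abs(z), log.p = TRUE)) / log(10)
}

#' Benjamini-Hochberg adjustment at a stated family size
#'
#' Step-up BH adjusted P-values, \eqn{\tilde p_{(i)} = \min_{j \ge i}
#' \{ p_{(j)}\, m/j \}} capped at 1, where the family size `m_total` may
#' exceed the number of supplied P-values — the partial-table case where only
#' the top of a larger scan is in hand (the supplied values must then be the
#' *smallest* `length(p)` P-values of the family for the adjustment to be
#' exact).
#'
#' @param p P-values in (0, 1].
#' @param m_total Family size; at least `length(p)` (default: exactly that,
#'   giving ordinary BH).
#' @return Adjusted P-values in input order.
#' @examples
#' bh_adjust(c(3.92e-12, 1.39e-8), m_total = 9952)
#' @export
bh_adjust <- function(p, m_total = length(p)) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("P-values must lie in (0, 1].")
  }
  if (m_total < length(p)) {
    abort("m_total must be at least the number of supplied P-values.")
  }
  o <- order(p)
  adj <- p[o] * m_total / seq_along(p)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(length(p))
  out[o] <- adj
  # guard the adj >= p identity against one-ulp rounding in p * m/j
  pmax(out, p)
}

#' Odds ratio confidence interval from the printed OR and z
#'
#' Recovers the Wald interval implied by a published odds ratio and its
#' z-score: \eqn{\beta = \ln OR}, \eqn{SE = |\beta/z|}, CI
#' \eqn{\exp(\beta \pm z_{1-\alpha/2} SE)}. `OR = 1` gives the degenerate
#' interval (1, 1) and is flagged with a warning; `z = 0` is an error (the
#' SE is undefined).
#'
#' @param or Odds ratio(s).
#' @param z z-score(s), same length.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `or`, `beta`, `se`, `ci_low`, `ci_high`.
#' @examples
#' or_ci_from_beta_z(1.147, 5.653)  # ABO-style interval
#' @export
or_ci_from_beta_z <- function(or, z, level = 0.95) {
  stopifnot(length(or) == length(z))
  if (any(z == 0)) abort("z = 0: the implied standard error is undefined.")
  beta <- log(or)
  if (any(beta == 0)) {
    warn("OR = 1 gives a degenerate (1, 1) interval.")
  }
  se <- abs(beta / z)
  q <- qnorm(1 - (1 - level) / 2)
  tibble(or = or, beta = beta, se = se,
         ci_low = exp(beta - q * se), ci_high = exp(beta + q * se))
}

#' Summary-statistics TWAS for one gene
#'
#' Combines a gene's expression-model weights with GWAS z-scores and an LD
#' reference into a gene-level association. With dosage-scale weights
#' \eqn{w_l}, panel dosage SDs \eqn{\sigma_l} and LD \eqn{\rho_{ll'}},
#' \deqn{z_g = \frac{\sum_l w_l \sigma_l z_l}{\sigma_g},\qquad
#'   \sigma_g^2 = \sum_{l,l'} w_l w_{l'} \sigma_l \sigma_{l'} \rho_{ll'},}
#' and the gene-level log-OR is \eqn{\beta_g = \sum_l w_l \sigma_l^2
#' \beta_l / \sigma_g^2} with \eqn{SE_g = \beta_g / z_g}. Models trained in
#' this package carry weights on the standardized-dosage scale
#' (`weight_scale = "standardized"`), for which the same algebra applies
#' with \eqn{\sigma_l} absorbed into the weights. GWAS effects are
#' harmonized to the model's effect alleles first (swapped alleles flip the
#' sign; mismatches are dropped); the retained fraction of total absolute
#' weight is reported and genes below `min_coverage` are flagged.
#'
#' @param model An `expr_model`.
#' @param gwas Summary-statistics tibble.
#' @param panel An [ld_panel()].
#' @param weight_scale `"standardized"` (default; weights per SD of dosage)
#'   or `"dosage"` (weights per allele copy).
#' @param min_coverage Weight-coverage fraction below which the gene is
#'   flagged (default 0.8).
#' @return A one-row tibble of class `twas_result`: `gene_id`, `zscore`,
#'   `beta_g`, `se_g`, `pvalue`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `n_model_snps`, `coverage`, `low_coverage`. Errors of class
#'   `twasmr_no_overlap` signal a gene none of whose model variants are
#'   testable.
#' @examples
#' # see vignette for end-to-end use
#' @export
summary_twas <- function(model, gwas, panel,
                         weight_scale = c("standardized", "dosage"),
                         min_coverage = 0.8) {
  weight_scale <- match.arg(weight_scale)
  w_tbl <- model$weights
  if (nrow(w_tbl) == 0) {
    abort(sprintf("Gene %s: model has no weights.", model$gene_id),
          class = "twasmr_no_overlap")
  }

  gw <- gwas |>
    filter(!is.na(.data$beta), !is.na(.data$se)) |>
    select("variant_id", gwas_effect = "effect_allele",
           gwas_other = "other_allele", "beta", "se")
  merged <- inner_join(w_tbl, gw, by = "variant_id") |>
    filter(panel_has(panel, .data$variant_id))
  same <- merged$effect_allele == merged$gwas_effect &
    merged$other_allele == merged$gwas_other
  swapped <- merged$effect_allele == merged$gwas_other &
    merged$other_allele == merged$gwas_effect
  merged <- merged |>
    mutate(beta = ifelse(swapped, -.data$beta, .data$beta)) |>
    filter(same | swapped)

  coverage <- sum(abs(merged$weight)) / sum(abs(w_tbl$weight))
  if (nrow(merged) == 0) {
    abort(sprintf("Gene %s: no model variant present in both GWAS and panel.",
                  model$gene_id),
          class = "twasmr_no_overlap")
  }

  ids <- merged$variant_id
  w <- merged$weight
  z_l <- merged$beta / merged$se
  sig <- panel_sd(panel, ids)
  R <- panel_cor(panel, ids)
  if (weight_scale == "standardized") {
    # per-SD weights: sigma_l cancels except through the correlations
    sig_for_num <- rep(1, length(w))
  } else {
    sig_for_num <- sig
  }
  var_g <- as.numeric(t(w * sig_for_num) %*% R %*% (w * sig_for_num))
  if (var_g <= 0) {
    abort(sprintf("Gene %s: non-positive predicted-expression variance (inconsistent LD).",
                  model$gene_id))
  }
  sigma_g <- sqrt(var_g)
  zscore <- sum(w * sig_for_num * z_l) / sigma_g
  # gene-level effect per SD of predicted expression
  beta_scale <- if (weight_scale == "standardized") sig else sig^2
  beta_g <- sum(w * beta_scale * merged$beta) / var_g
  se_g <- if (zscore != 0) abs(beta_g / zscore) else NA_real_
  pvalue <- z_to_p(zscore)
  q <- qnorm(0.975)

  out <- tibble(
    gene_id = model$gene_id, tissue = model$tissue,
    framework = model$framework,
    zscore = zscore, beta_g = beta_g, se_g = se_g, pvalue = pvalue,
    odds_ratio = exp(beta_g),
    ci_low = exp(beta_g - q * se_g), ci_high = exp(beta_g + q * se_g),
    n_model_snps = nrow(merged), coverage = coverage,
    low_coverage = coverage < min_coverage
  )
  class(out) <- c("twas_result", class(out))
  out
}

#' Transcriptome-wide scan over a set of gene models
#'
#' Runs [summary_twas()] for every model, applies [bh_adjust()] across the
#' scan at family size `m_total`, and labels significance at `fdr_threshold`.
#' Genes with no testable variant are reported in the `"skipped"` attribute,
#' never silently dropped.
#'
#' @param models List of `expr_model` objects.
#' @param gwas,panel,weight_scale As in [summary_twas()].
#' @param m_total BH family size (default: number of genes tested).
#' @param fdr_threshold Significance label threshold (default 0.10).
#' @return A `twas_result` tibble, one row per tested gene, with
#'   `fdr_adjusted_p` and `significant` columns, sorted by P-value.
#' @export
twas_scan <- function(models, gwas, panel, m_total = NULL,
                      fdr_threshold = 0.10,
                      weight_scale = c("standardized", "dosage")) {
  weight_scale <- match.arg(weight_scale)
  skipped <- list()
  rows <- map(models, function(m) {
    tryCatch(summary_twas(m, gwas, panel, weight_scale = weight_scale),
             twasmr_no_overlap = function(e) {
               skipped[[length(skipped) + 1L]] <<-
                 tibble(gene_id = m$gene_id, reason = conditionMessage(e))
               NULL
             })
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) > 0) {
    out <- out |>
      mutate(fdr_adjusted_p = bh_adjust(.data$pvalue,
                                        m_total %||% nrow(out)),
             significant = .data$fdr_adjusted_p < fdr_threshold) |>
      arrange(.data$pvalue)
  }
  class(out) <- c("twas_result", class(out))
  attr(out, "skipped") <- list_rbind(skipped)
  attr(out, "m_total") <- m_total %||% nrow(out)
  out
}
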