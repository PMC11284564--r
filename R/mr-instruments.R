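#' Build an instrument set for Mendelian randomization
#'
#' Selects independent exposure-associated variants by LD clumping
#' (`p_threshold = 5e-8`, pairwise r-squared < 0.01 within 250 kb by
#' default), harmonizes the outcome effects to the exposure's effect
#' alleles, and optionally restricts to — or excludes — a gene locus
#' (variants whose position lies within `locus_window_bp` of the gene body,
#' boundaries inclusive). Estimation downstream requires at least three
#' instruments; the set itself may hold fewer (the count is reported and the
#' estimators refuse).
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param panel An [ld_panel()] for clumping.
#' @param p_threshold,r2_threshold,window_bp Clumping thresholds
#'   (see [ld_clump()]).
#' @param locus Optional locus restriction: a list or one-row tibble with
#'   `chrom`, `gene_start`, `gene_end`.
#' @param exclude_locus Optional locus exclusion, same shape.
#' @param locus_window_bp Cis window around the gene body (default 1 Mb,
#'   inclusive on both sides).
#' @param exposure_id Label stored on the set.
#' @return A tibble of class `instrument_set` with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; attributes record the exposure label and counts at
#'   each filtering step.
#' @examples
#' # see vignette for end-to-end use
#' @export
build_instruments <- function(exposure, outcome, panel,
                              p_threshold = 5e-8, r2_threshold = 0.01,
                              window_bp = 250000,
                              locus = NULL, exclude_locus = NULL,
                              locus_window_bp = 1e6,
                              exposure_id = "exposure") {
  clumped <- ld_clump(exposure, panel, p_threshold = p_threshold,
                      r2_threshold = r2_threshold, window_bp = window_bp)
  n_clumped <- nrow(clumped)

  if (!is.null(locus)) {
    locus <- as.list(locus)
    clumped <- filter(clumped, .data$chrom == locus$chrom,
                      .data$pos >= locus$gene_start - locus_window_bp,
                      .data$pos <= locus$gene_end + locus_window_bp)
  }
  if (!is.null(exclude_locus)) {
    excl <- as.list(exclude_locus)
    clumped <- filter(clumped, !(.data$chrom == excl$chrom &
                                   .data$pos >= excl$gene_start - locus_window_bp &
                                   .data$pos <= excl$gene_end + locus_window_bp))
  }

  iv <- harmonize_effects(clumped, outcome) |>
    select("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta_exp", "se_exp", "beta_out", "se_out")
  structure(iv,
            class = c("instrument_set", class(iv)),
            exposure_id = exposure_id,
            n_clumped = n_clumped,
            n_after_locus = nrow(clumped),
            dropped_harmonization = attr(iv, "dropped"))
}

#' Construct an instrument set from effect pairs
#'
#' Wraps already-harmonized exposure/outcome effect pairs (e.g. simulated
#' ones) as an `instrument_set` for the estimators.
#'
#' @param tbl Tibble with columns `beta_exp`, `se_exp`, `beta_out`, `se_out`
#'   (a `variant_id` column is added if missing).
#' @param exposure_id Label.
#' @return An `instrument_set` tibble.
#' @export
as_instrument_set <- function(tbl, exposure_id = "exposure") {
  needed <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  tbl <- as_tibble(tbl)
  if (!"variant_id" %in% names(tbl)) {
    tbl <- mutate(tbl, variant_id = sprintf("iv%03d", row_number()))
  }
  structure(tbl, class = c("instrument_set", setdiff(class(tbl), "instrument_set")),
            exposure_id = exposure_id)
}

# Refusal contract shared by every estimator.
check_min_ivs <- function(iv, method, min_iv = 3L) {
  if (nrow(iv) < min_iv) {
    abort(sprintf(
      "MR (%s) refused: %d instrument(s) available, at least %d independent IVs required.",
      method, nrow(iv), min_iv),
      class = "mr_refusal")
  }
  invisible(TRUE)
}

#' Per-instrument Wald ratios
#'
#' The per-IV causal estimate \eqn{\theta_j = \beta_{out,j}/\beta_{exp,j}}
#' with first-order standard error \eqn{|SE_{out,j}/\beta_{exp,j}|} (the
#' exposure uncertainty is ignored, as instruments are genome-wide
#' significant by construction). Instruments with a zero exposure effect are
#' excluded with a reason.
#'
#' @param iv An `instrument_set`.
#' @return The set with columns `ratio` and `ratio_se` appended; excluded
#'   rows are in the `"excluded"` attribute.
#' @export
mr_wald_ratios <- function(iv) {
  zero <- iv$beta_exp == 0
  out <- iv[!zero, , drop = FALSE] |>
    mutate(ratio = .data$beta_out / .data$beta_exp,
           ratio_se = abs(.data$se_out / .data$beta_exp))
  attr(out, "excluded") <- tibble(variant_id = iv$variant_id[zero],
                                  reason = "zero exposure effect")
  out
}

new_mr_estimate <- function(method, estimate, se, n_iv,
                            intercept = NA_real_, intercept_p = NA_real_,
                            extra = list()) {
  q <- qnorm(0.975)
  out <- tibble(
    method = method, estimate = estimate, se = se,
    pvalue = z_to_p(estimate / se),
    or = exp(estimate), ci_low = exp(estimate - q * se),
    ci_high = exp(estimate + q * se),
    n_iv = n_iv, intercept = intercept, intercept_p = intercept_p
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("mr_estimate", class(out))
  out
}
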