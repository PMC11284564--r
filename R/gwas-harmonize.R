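#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome dataset to the exposure dataset's effect alleles,
#' matching variants on chromosome and position. If the outcome's allele pair
#' is the exposure's swapped (effect/other reversed), the outcome beta sign
#' is flipped and its frequency complemented. Palindromic (strand-ambiguous,
#' A/T or C/G) variants whose exposure or outcome frequency falls in the
#' ambiguity band (0.4, 0.6) are dropped — the strand cannot be resolved.
#' Incompatible allele sets are excluded with a reason code. Harmonizing an
#' already-aligned pair is a no-op, so the operation is idempotent.
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param ambiguity_band Frequency band within which palindromic variants are
#'   considered unresolvable (default `c(0.4, 0.6)`, exclusive).
#' @return A tibble with one row per retained variant: `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele` (exposure orientation),
#'   `beta_exp`, `se_exp`, `pvalue_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `pvalue_out`, `eaf_out`. Dropped variants (with reason codes
#'   `"palindromic-ambiguous"` or `"incompatible-alleles"`) are in the
#'   `"dropped"` attribute.
#' @examples
#' exp <- tibble::tibble(variant_id = "v1", chrom = "1", pos = 100,
#'   effect_allele = "A", other_allele = "G", beta = 0.2, se = 0.05,
#'   pvalue = 1e-5, eaf = 0.3, n = 1000)
#' out <- dplyr::mutate(exp, effect_allele = "G", other_allele = "A",
#'   beta = 0.3, eaf = 0.7)
#' harmonize_effects(exp, out)$beta_out  # -0.3
#' @export
harmonize_effects <- function(exposure, outcome, ambiguity_band = c(0.4, 0.6)) {
  exp_tbl <- exposure |>
    select("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           beta_exp = "beta", se_exp = "se", pvalue_exp = "pvalue",
           eaf_exp = "eaf")
  out_tbl <- outcome |>
    select("chrom", "pos", out_effect = "effect_allele",
           out_other = "other_allele", beta_out = "beta", se_out = "se",
           pvalue_out = "pvalue", eaf_out = "eaf")
  joined <- inner_join(exp_tbl, out_tbl, by = c("chrom", "pos"))

  same <- joined$effect_allele == joined$out_effect &
    joined$other_allele == joined$out_other
  swapped <- joined$effect_allele == joined$out_other &
    joined$other_allele == joined$out_effect
  palindromic <- is_palindromic(joined$effect_allele, joined$other_allele)
  ambiguous <- palindromic &
    (in_band(joined$eaf_exp, ambiguity_band) |
       in_band(joined$eaf_out, ambiguity_band))

  reason <- rep(NA_character_, nrow(joined))
  reason[!same & !swapped] <- "incompatible-alleles"
  reason[is.na(reason) & ambiguous] <- "palindromic-ambiguous"

  aligned <- joined |>
    mutate(
      beta_out = ifelse(swapped, -.data$beta_out, .data$beta_out),
      eaf_out = ifelse(swapped, 1 - .data$eaf_out, .data$eaf_out)
    ) |>
    select(-"out_effect", -"out_other")

  dropped <- tibble(variant_id = joined$variant_id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  kept <- aligned[is.na(reason), , drop = FALSE]
  attr(kept, "dropped") <- dropped
  kept
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

in_band <- function(x, band) !is.na(x) & x > band[1] & x < band[2]
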