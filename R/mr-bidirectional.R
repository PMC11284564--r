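#' Bidirectional Mendelian randomization between two traits
#'
#' Runs MR in both directions — instruments for trait A tested against trait
#' B, and vice versa — with each requested estimator, optionally restricting
#' instruments to a gene locus or excluding one (e.g. to ask whether an
#' inferred causal effect is driven by a single gene). Directions whose
#' instrument set has fewer than three members are reported as refusals, not
#' estimates.
#'
#' @param gwas_a,gwas_b Summary-statistics tibbles for the two traits.
#' @param panel An [ld_panel()] used for clumping in both directions.
#' @param methods Estimators to run (see [mr_all_methods()]).
#' @param p_threshold,r2_threshold,window_bp Instrument-selection thresholds.
#' @param locus,exclude_locus,locus_window_bp Optional locus restriction /
#'   exclusion applied to both directions (see [build_instruments()]).
#' @param labels Length-2 character, names of the traits.
#' @param n_boot,seed Passed to bootstrap-based estimators.
#' @return A tibble of class `mr_estimate` with a `direction` column
#'   (`"A->B"`, `"B->A"`); refusals are recorded in the `"refusals"`
#'   attribute (direction, reason, instrument count).
#' @export
bidirectional_mr <- function(gwas_a, gwas_b, panel,
                             methods = c("ivw", "wme", "egger"),
                             p_threshold = 5e-8, r2_threshold = 0.01,
                             window_bp = 250000,
                             locus = NULL, exclude_locus = NULL,
                             locus_window_bp = 1e6,
                             labels = c("A", "B"),
                             n_boot = 1000L, seed = 1L) {
  run_direction <- function(exposure, outcome, dir_label) {
    iv <- build_instruments(exposure, outcome, panel,
                            p_threshold = p_threshold,
                            r2_threshold = r2_threshold,
                            window_bp = window_bp,
                            locus = locus, exclude_locus = exclude_locus,
                            locus_window_bp = locus_window_bp,
                            exposure_id = dir_label)
    tryCatch(
      mutate(mr_all_methods(iv, methods = methods, n_boot = n_boot,
                            seed = seed),
             direction = dir_label, n_iv_available = nrow(iv)),
      mr_refusal = function(e) {
        structure(tibble(), refusal = tibble(direction = dir_label,
                                             n_iv = nrow(iv),
                                             reason = conditionMessage(e)))
      })
  }
  ab <- run_direction(gwas_a, gwas_b, paste0(labels[1], "->", labels[2]))
  ba <- run_direction(gwas_b, gwas_a, paste0(labels[2], "->", labels[1]))
  out <- bind_rows(ab, ba)
  refusals <- bind_rows(attr(ab, "refusal") %||% tibble(),
                        attr(ba, "refusal") %||% tibble())
  class(out) <- unique(c("mr_estimate", class(out)))
  attr(out, "refusals") <- refusals
  out
}
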