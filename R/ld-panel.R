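#' LD reference panel
#'
#' Wraps either genotype dosages or a precomputed correlation matrix, and
#' serves per-variant dosage standard deviations and pairwise dosage
#' correlations to the TWAS and clumping machinery.
#'
#' @param x A [simulate_genotypes()] result, a samples x variants dosage
#'   matrix (column names = variant IDs), or a correlation matrix (symmetric,
#'   unit diagonal; then `sds` supplies the dosage SDs, default 1).
#' @param variants Variant metadata tibble (`variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`); taken from `x` when it is a
#'   `sim_genotypes`.
#' @param sds Optional named numeric vector of dosage standard deviations
#'   (only used with a correlation-matrix input).
#' @return An object of class `ld_panel`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples = 100, n_variants = 10,
#'                                    n_genes = 1, seed = 6))
#' panel <- ld_panel(g)
#' ld_r2(panel, "v00001", "v00002")
#' @export
ld_panel <- function(x, variants = NULL, sds = NULL) {
  if (inherits(x, "sim_genotypes")) {
    variants <- x$variants
    x <- x$dosages
  }
  if (is.null(variants)) abort("Variant metadata is required.")
  variants <- as_tibble(variants)
  if (!is.matrix(x)) abort("Dosages/correlations must be a matrix.")

  is_cor <- nrow(x) == ncol(x) &&
    max(abs(diag(x) - 1)) < 1e-8 && max(abs(x - t(x))) < 1e-8 &&
    all(abs(x) <= 1 + 1e-8)
  if (is_cor) {
    if (is.null(colnames(x))) colnames(x) <- rownames(x) <- variants$variant_id
    sds <- sds %||% setNames(rep(1, ncol(x)), colnames(x))
    obj <- list(cormat = x, dosages = NULL, sds = sds, variants = variants)
  } else {
    if (is.null(colnames(x))) colnames(x) <- variants$variant_id
    sdv <- apply(x, 2L, sd)
    obj <- list(cormat = NULL, dosages = x,
                sds = setNames(sdv, colnames(x)), variants = variants)
  }
  structure(obj, class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  src <- if (is.null(x$dosages)) "precomputed correlations" else
    sprintf("%d dosage samples", nrow(x$dosages))
  cat(sprintf("<ld_panel> %d variants (%s)\n", nrow(x$variants), src))
  invisible(x)
}

panel_has <- function(panel, ids) ids %in% panel$variants$variant_id

panel_check <- function(panel, ids) {
  miss <- setdiff(ids, panel$variants$variant_id)
  if (length(miss) > 0) {
    abort(sprintf("Variant(s) absent from LD panel: %s",
                  paste(head(miss, 5L), collapse = ", ")))
  }
  invisible(TRUE)
}

# Correlation submatrix for a set of variant IDs.
panel_cor <- function(panel, ids) {
  panel_check(panel, ids)
  if (!is.null(panel$cormat)) return(panel$cormat[ids, ids, drop = FALSE])
  X <- panel$dosages[, ids, drop = FALSE]
  sdv <- panel$sds[ids]
  R <- suppressWarnings(cor(X))
  # monomorphic columns yield NA correlations; treat as uncorrelated
  R[is.na(R)] <- 0
  diag(R) <- 1
  R
}

# Dosage SDs for a set of variant IDs.
panel_sd <- function(panel, ids) {
  panel_check(panel, ids)
  panel$sds[ids]
}

#' Squared LD correlation between two variants
#'
#' Squared Pearson correlation of the panel's dosage vectors (or the squared
#' entry of the precomputed correlation matrix).
#'
#' @param panel An [ld_panel()].
#' @param v1,v2 Variant IDs.
#' @return A number in \[0, 1\].
#' @export
ld_r2 <- function(panel, v1, v2) {
  panel_check(panel, c(v1, v2))
  unname(panel_cor(panel, c(v1, v2))[1L, 2L]^2)
}

#' Greedy LD clumping of summary statistics
#'
#' Selects approximately independent association signals: variants passing
#' `p_threshold` are visited in order of ascending P-value (ties broken by
#' chromosome then position), and a variant is accepted iff its LD r-squared
#' with every already-accepted variant on the same chromosome within
#' `window_bp` (center-to-center, inclusive) is below `r2_threshold`. Default
#' thresholds: genome-wide significance 5e-8, r-squared 0.01, window 250 kb.
#'
#' @param stats Summary-statistics tibble.
#' @param panel An [ld_panel()] containing the candidate variants.
#' @param p_threshold,r2_threshold,window_bp Clumping thresholds.
#' @return The subset of `stats` rows retained as independent index variants,
#'   sorted by P-value; empty input or no passing variant yields an empty
#'   tibble (not an error).
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples = 500, n_variants = 20,
#'                                    n_genes = 2, seed = 8))
#' ph <- simulate_case_control(g, simulate_expression(g, g$config), g$config)
#' ss <- make_gwas_summary(g, ph)
#' ld_clump(ss, ld_panel(g), p_threshold = 0.5)
#' @export
ld_clump <- function(stats, panel, p_threshold = 5e-8, r2_threshold = 0.01,
                     window_bp = 250000) {
  cand <- stats |>
    filter(!is.na(.data$pvalue), .data$pvalue < p_threshold) |>
    filter(panel_has(panel, .data$variant_id)) |>
    arrange(.data$pvalue, .data$chrom, .data$pos)
  if (nrow(cand) == 0) return(cand)

  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    near <- accepted[cand$chrom[accepted] == cand$chrom[i] &
                       abs(cand$pos[accepted] - cand$pos[i]) <= window_bp]
    ok <- TRUE
    for (j in near) {
      if (ld_r2(panel, cand$variant_id[i], cand$variant_id[j]) >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  cand[accepted, , drop = FALSE]
}
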