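# Small shared fixtures, built in code.

tiny_config <- function(seed = 1L, ...) {
  sim_config(n_samples = 300, n_variants = 40, n_genes = 4,
             heritability = 0.5, seed = seed, ...)
}

# Deterministic hand-written summary-statistics rows.
sumstats_row <- function(variant_id = "v1", chrom = "1", pos = 100,
                         effect_allele = "A", other_allele = "G",
                         beta = 0.1, se = 0.05, pvalue = NULL,
                         eaf = 0.3, n = 1000) {
  tibble::tibble(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    beta = beta, se = se,
    pvalue = pvalue %||% 2 * stats::pnorm(-abs(beta / se)),
    eaf = eaf, n = n, monomorphic = FALSE)
}

# LD panel from an explicit correlation matrix.
cor_panel <- function(R, pos = NULL, chrom = "1") {
  m <- nrow(R)
  ids <- sprintf("v%d", seq_len(m))
  dimnames(R) <- list(ids, ids)
  variants <- tibble::tibble(
    variant_id = ids, chrom = chrom,
    pos = pos %||% seq_len(m) * 1000,
    effect_allele = "A", other_allele = "G", eaf = 0.3)
  ld_panel(R, variants)
}

`%||%` <- rlang::`%||%`

# Ground-truth expression model for one simulated gene (tissue1 weights).
truth_model <- function(expr_sim, geno, j) {
  gid <- expr_sim$genes$gene_id[j]
  wt <- expr_sim$truth$weights
  w <- wt[wt$gene_id == gid & wt$tissue == "tissue1", , drop = FALSE]
  tbl <- dplyr::left_join(
    dplyr::select(w, "variant_id", "weight"),
    dplyr::select(geno$variants, "variant_id", "chrom", "pos",
                  "effect_allele", "other_allele"),
    by = "variant_id")
  twasmr:::new_expr_model(
    list(gene_id = gid, chrom = "1",
         gene_start = expr_sim$genes$gene_start[j],
         gene_end = expr_sim$genes$gene_end[j]),
    "tissue1", "elastic_net", tbl, cv_r = 0.9, cv_p = 1e-10)
}
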