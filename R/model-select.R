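#' Select the best imputable model for a gene
#'
#' Among candidate models of one gene (typically one per framework), returns
#' the model with the highest cross-validated correlation `cv_r`. Ties are
#' broken deterministically by framework order (`elastic_net` <
#' `cross_tissue_group` < `similarity_weighted`). If even the best model
#' fails the imputability rule — `cv_r > 0.1` and `cv_p < 0.05` — the gene is
#' not imputable and `NULL` is returned.
#'
#' @param models A list of `expr_model` objects for one gene.
#' @return The selected `expr_model`, or `NULL` if no candidate is imputable.
#' @examples
#' # see vignette for end-to-end use
#' @export
select_best_model <- function(models) {
  models <- purrr::compact(models)
  if (length(models) == 0) abort("At least one candidate model is required.")
  frameworks <- c("elastic_net", "cross_tissue_group", "similarity_weighted")
  ord <- order(-map_dbl(models, "cv_r"),
               match(purrr::map_chr(models, "framework"), frameworks))
  best <- models[[ord[1]]]
  if (!isTRUE(best$imputable)) return(NULL)
  best
}

#' Flatten expression models into a weight table
#'
#' One row per (gene, tissue, framework, variant) with the model weight and
#' its cross-validation performance — the interchange format written to and
#' read from disk.
#'
#' @param models A list of `expr_model` objects.
#' @return A tibble with columns `gene_id`, `tissue`, `framework`,
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `weight`,
#'   `cv_r`, `cv_p`.
#' @export
weights_table <- function(models) {
  list_rbind(map(models, function(m) {
    if (nrow(m$weights) == 0) return(tibble())
    m$weights |>
      mutate(gene_id = m$gene_id, tissue = m$tissue, framework = m$framework,
             cv_r = m$cv_r, cv_p = m$cv_p,
             gene_start = m$gene_start, gene_end = m$gene_end) |>
      relocate("gene_id", "tissue", "framework")
  }))
}

#' Rebuild expression models from a weight table
#'
#' Inverse of [weights_table()]: reconstructs one `expr_model` per
#' (gene, tissue, framework) group. Round-trips losslessly.
#'
#' @param tbl A tibble as produced by [weights_table()].
#' @return A list of `expr_model` objects.
#' @export
models_from_weights <- function(tbl) {
  groups <- tbl |>
    dplyr::group_split(.data$gene_id, .data$tissue, .data$framework)
  map(groups, function(g) {
    gene <- list(gene_id = g$gene_id[1], chrom = g$chrom[1],
                 gene_start = g$gene_start[1], gene_end = g$gene_end[1])
    new_expr_model(gene, g$tissue[1], g$framework[1],
                   select(g, "variant_id", "chrom", "pos", "effect_allele",
                          "other_allele", "weight"),
                   g$cv_r[1], g$cv_p[1])
  })
}
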