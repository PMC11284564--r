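#' Phenome-wide association scan for one gene model
#'
#' Tests a gene's predicted expression against every phenotype in a catalog
#' of phecode-labelled GWAS summary statistics — one [summary_twas()] per
#' phenotype — and adjusts across phenotypes within the scan by
#' Benjamini-Hochberg. Phenotypes with no overlapping variant are reported
#' as skipped.
#'
#' @param model An `expr_model`.
#' @param catalog A tibble with columns `phecode` (unique), `label`,
#'   `category`, and a list-column `gwas` of summary-statistics tibbles; see
#'   [phewas_catalog()].
#' @param panel An [ld_panel()].
#' @param weight_scale As in [summary_twas()].
#' @return A tibble of class `phewas_result`, one row per tested phenotype
#'   (`gene_id`, `phecode`, `label`, `category`, `zscore`, `pvalue`,
#'   `adjusted_p`, `direction`), sorted by P-value; skipped phenotypes in
#'   the `"skipped"` attribute.
#' @export
phewas_scan <- function(model, catalog, panel,
                        weight_scale = c("standardized", "dosage")) {
  weight_scale <- match.arg(weight_scale)
  if (nrow(catalog) == 0) abort("The phenotype catalog is empty.")
  if (anyDuplicated(catalog$phecode)) abort("Phecodes must be unique.")

  skipped <- list()
  rows <- map(seq_len(nrow(catalog)), function(i) {
    tryCatch({
      r <- summary_twas(model, catalog$gwas[[i]], panel,
                        weight_scale = weight_scale)
      tibble(gene_id = r$gene_id, phecode = catalog$phecode[i],
             label = catalog$label[i], category = catalog$category[i],
             zscore = r$zscore, pvalue = r$pvalue,
             direction = ifelse(r$zscore >= 0, "+", "-"))
    }, twasmr_no_overlap = function(e) {
      skipped[[length(skipped) + 1L]] <<-
        tibble(phecode = catalog$phecode[i], reason = conditionMessage(e))
      NULL
    })
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) > 0) {
    out <- out |>
      mutate(adjusted_p = bh_adjust(.data$pvalue)) |>
      arrange(.data$pvalue)
  }
  class(out) <- c("phewas_result", class(out))
  attr(out, "skipped") <- list_rbind(skipped)
  out
}

#' Assemble a phenotype catalog
#'
#' @param phecode,label,category Character vectors, one entry per phenotype.
#' @param gwas List of summary-statistics tibbles, same length.
#' @return A catalog tibble for [phewas_scan()].
#' @export
phewas_catalog <- function(phecode, label, category, gwas) {
  stopifnot(length(phecode) == length(gwas))
  if (anyDuplicated(phecode)) abort("Phecodes must be unique.")
  tibble(phecode = phecode, label = label, category = category, gwas = gwas)
}

#' Read a phenotype-catalog manifest
#'
#' The manifest is a TSV with columns `phecode`, `label`, `category`,
#' `path` (per-phenotype summary-statistics files, relative paths resolved
#' against the manifest's directory).
#'
#' @param path Manifest file path.
#' @return A catalog tibble for [phewas_scan()].
#' @export
read_phewas_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("phecode", "label", "category", "path")
  if (!all(needed %in% names(man))) {
    abort(sprintf("Manifest must have columns: %s",
                  paste(needed, collapse = ", ")))
  }
  base <- dirname(path)
  gwas <- map(man$path, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_summary_stats(full)
  })
  phewas_catalog(man$phecode, man$label, man$category, gwas)
}
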