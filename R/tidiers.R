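#' Tidy an expression model
#'
#' One row per model variant with its weight — the broom convention for a
#' fitted object's term-level summary.
#'
#' @param x An `expr_model`.
#' @param ... Unused.
#' @return A tibble of weights with gene/tissue/framework identifiers.
#' @method tidy expr_model
#' @export
tidy.expr_model <- function(x, ...) {
  x$weights |>
    mutate(gene_id = x$gene_id, tissue = x$tissue, framework = x$framework) |>
    relocate("gene_id", "tissue", "framework")
}

#' @rdname tidy.expr_model
#' @return For `glance()`: a one-row tibble with the model-level summary
#'   (`cv_r`, `cv_p`, `imputable`, number of nonzero weights).
#' @method glance expr_model
#' @export
glance.expr_model <- function(x, ...) {
  tibble(gene_id = x$gene_id, tissue = x$tissue, framework = x$framework,
         cv_r = x$cv_r, cv_p = x$cv_p, imputable = x$imputable,
         n_weights = nrow(x$weights))
}

#' Tidy MR estimates
#'
#' `mr_estimate` tibbles are already term-per-row; `tidy()` standardizes the
#' column names to broom's (`term`, `estimate`, `std.error`, `p.value`) and
#' `glance()` summarizes the run.
#'
#' @param x An `mr_estimate` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  as_tibble(x) |>
    rename(term = "method", std.error = "se", p.value = "pvalue")
}

#' @rdname tidy.mr_estimate
#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(n_methods = length(unique(x$method)),
         n_iv = max(x$n_iv),
         min_p = min(x$pvalue))
}

#' Tidy a TWAS scan
#'
#' @param x A `twas_result` tibble.
#' @param ... Unused.
#' @return `tidy()`: the result with broom-style names; `glance()`: one row
#'   with scan-level counts.
#' @method tidy twas_result
#' @export
tidy.twas_result <- function(x, ...) {
  as_tibble(x) |>
    rename(term = "gene_id", statistic = "zscore", p.value = "pvalue")
}

#' @rdname tidy.twas_result
#' @method glance twas_result
#' @export
glance.twas_result <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_significant = if ("significant" %in% names(x))
           sum(x$significant) else NA_integer_,
         m_total = attr(x, "m_total") %||% nrow(x))
}
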