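#' Manhattan-style plot of TWAS results
#'
#' One point per gene at its genomic start position, height
#' \eqn{-\log_{10} P}, colored by significance at the scan's FDR threshold.
#'
#' @param object A `twas_result` tibble from [twas_scan()] (needs a
#'   `gene_id` column; positions are taken from `gene_start` when present,
#'   otherwise genes are spaced evenly).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twas_result
#' @export
autoplot.twas_result <- function(object, ...) {
  df <- as_tibble(object)
  if (!"gene_start" %in% names(df)) {
    df <- mutate(df, gene_start = row_number())
  }
  sig <- "significant" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gene_start, y = -log10(.data$pvalue))) +
    ggplot2::geom_point(if (sig) ggplot2::aes(color = .data$significant)) +
    ggplot2::labs(x = "gene position (bp)",
                  y = expression(-log[10](italic(P))),
                  color = "FDR significant") +
    ggplot2::theme_minimal()
  p
}

#' @rdname autoplot.twas_result
#' @param x A `twas_result`.
#' @param y Ignored.
#' @method plot twas_result
#' @export
plot.twas_result <- function(x, y, ...) print(autoplot.twas_result(x, ...))

#' Forest plot of MR estimates
#'
#' Odds ratios with 95% confidence intervals, one row per method (and per
#' direction/gene when those columns are present).
#'
#' @param estimates An `mr_estimate` tibble.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(estimates) {
  df <- as_tibble(estimates) |>
    mutate(label = paste0(
      .data$method,
      if ("direction" %in% names(estimates)) paste0(" [", .data$direction, "]") else "",
      if ("gene_id" %in% names(estimates)) paste0(" ", .data$gene_id) else ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an instrument set with fitted MR slopes
#'
#' Exposure effects against outcome effects (error bars = 1 SE), overlaid
#' with the fitted line of each supplied estimate (Egger lines use their
#' intercept; others pass through the origin).
#'
#' @param iv An `instrument_set`.
#' @param estimates Optional `mr_estimate` tibble to overlay.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(iv, estimates = NULL) {
  df <- as_tibble(iv)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           width = 0, color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "effect on exposure", y = "effect on outcome") +
    ggplot2::theme_minimal()
  if (!is.null(estimates)) {
    lines <- as_tibble(estimates) |>
      mutate(intercept = ifelse(is.na(.data$intercept), 0, .data$intercept))
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$estimate, intercept = .data$intercept,
                   color = .data$method))
  }
  p
}

#' PheWAS plot by phenotype category
#'
#' @param object A `phewas_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phewas_result
#' @export
autoplot.phewas_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = -log10(.data$pvalue),
                                   shape = .data$direction)) +
    ggplot2::geom_jitter(width = 0.2, height = 0) +
    ggplot2::scale_shape_manual(values = c(`+` = 24, `-` = 25)) +
    ggplot2::labs(x = "phenotype category",
                  y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
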