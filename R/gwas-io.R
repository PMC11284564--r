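#' Read and write GWAS summary statistics
#'
#' The on-disk format is a TSV with header columns `variant_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `eaf`,
#' `n`. Reading validates each row: `se` must be positive, `pvalue` in
#' (0, 1\], `eaf` in (0, 1), `pos` positive. Invalid rows are dropped with a
#' per-row report (file line numbers) attached as the `"rejected"` attribute
#' and surfaced as a warning; a missing required column is an error. Rows
#' with `NA` statistics but `monomorphic = TRUE` pass through (flagged
#' missingness is legitimate).
#'
#' @param path File path.
#' @return A tibble of summary statistics in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' cfg <- sim_config(n_samples = 200, n_variants = 10, n_genes = 1, seed = 5)
#' g <- simulate_genotypes(cfg)
#' ss <- make_gwas_summary(g, simulate_case_control(g, simulate_expression(g, cfg), cfg))
#' write_summary_stats(ss, f)
#' read_summary_stats(f)
#' @export
read_summary_stats <- function(path) {
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pvalue", "eaf", "n")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           variant_id = "c", chrom = "c", pos = "d",
                           effect_allele = "c", other_allele = "c",
                           beta = "d", se = "d", pvalue = "d", eaf = "d",
                           n = "d", .default = readr::col_guess()))
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("Summary-statistics file %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(tbl)
  bad_parse <- if (nrow(probs) > 0) unique(probs$row) else integer(0)

  mono <- if ("monomorphic" %in% names(tbl)) tbl$monomorphic %in% TRUE else
    rep(FALSE, nrow(tbl))
  reasons <- character(nrow(tbl))
  stat_na <- is.na(tbl$beta) | is.na(tbl$se) | is.na(tbl$pvalue)
  reasons[stat_na & !mono] <- "missing statistic"
  ok_stats <- !stat_na
  reasons[ok_stats & tbl$se <= 0] <- "se <= 0"
  reasons[ok_stats & reasons == "" &
            (tbl$pvalue <= 0 | tbl$pvalue > 1)] <- "pvalue outside (0, 1]"
  reasons[reasons == "" & (is.na(tbl$pos) | tbl$pos <= 0)] <- "pos <= 0"
  reasons[reasons == "" & !is.na(tbl$eaf) &
            (tbl$eaf <= 0 | tbl$eaf >= 1)] <- "eaf outside (0, 1)"
  reasons[seq_len(nrow(tbl)) %in% bad_parse] <- "unparseable field"

  bad <- which(reasons != "")
  rejected <- tibble(line = bad + 1L,  # +1 for the header line
                     variant_id = tbl$variant_id[bad], reason = reasons[bad])
  if (nrow(rejected) > 0) {
    warn(sprintf(
      "%d row(s) rejected while reading %s (see attr(., 'rejected')): %s",
      nrow(rejected), path,
      paste(sprintf("line %d [%s]", head(rejected$line, 5L),
                    head(rejected$reason, 5L)), collapse = "; ")))
  }
  out <- tbl[setdiff(seq_len(nrow(tbl)), bad), , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' @param stats A summary-statistics tibble.
#' @rdname read_summary_stats
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(stats, path, progress = FALSE)
  invisible(path)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-study effects for each variant under a common-effect model:
#' with weights \eqn{w_i = 1/SE_i^2}, the combined effect is
#' \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i} and its standard error
#' \eqn{(\sum w_i)^{-1/2}}; the P-value comes from the combined z. Effect
#' alleles must already be harmonized across studies: any variant whose
#' allele pair differs between studies is an error, never a silent flip.
#' Cochran's Q and I-squared are reported per variant but play no role in the
#' pooling.
#'
#' @param studies A list of summary-statistics tibbles (one per study), or a
#'   single tibble with a `study` column.
#' @return A combined summary-statistics tibble (one row per variant,
#'   ordered by chrom/pos) with extra columns `n_studies`, `q_stat`, `i2`.
#' @examples
#' s1 <- tibble::tibble(variant_id = "v1", chrom = "1", pos = 100,
#'   effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.1,
#'   pvalue = 0.32, eaf = 0.3, n = 1000)
#' s2 <- dplyr::mutate(s1, beta = 0.3, se = 0.2, n = 500)
#' meta_fixed_effect(list(s1, s2))
#' @export
meta_fixed_effect <- function(studies) {
  if (is.data.frame(studies)) {
    if (!"study" %in% names(studies)) {
      abort("A single-table input needs a `study` column.")
    }
    stacked <- as_tibble(studies)
  } else {
    if (length(studies) == 0) abort("At least one study is required.")
    stacked <- list_rbind(map(seq_along(studies), function(i) {
      mutate(as_tibble(studies[[i]]), study = paste0("study", i))
    }))
  }
  stacked <- filter(stacked, !is.na(.data$beta) & !is.na(.data$se))

  allele_check <- stacked |>
    group_by(.data$variant_id) |>
    summarise(n_allele_codings = dplyr::n_distinct(
      paste(.data$effect_allele, .data$other_allele)), .groups = "drop") |>
    filter(.data$n_allele_codings > 1)
  if (nrow(allele_check) > 0) {
    abort(sprintf(
      "Unharmonized effect alleles across studies for variant(s): %s. Harmonize before meta-analysis.",
      paste(head(allele_check$variant_id, 5L), collapse = ", ")))
  }

  stacked |>
    group_by(.data$variant_id, .data$chrom, .data$pos,
             .data$effect_allele, .data$other_allele) |>
    summarise(
      beta_c = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se_c = sqrt(1 / sum(1 / .data$se^2)),
      eaf = weighted.mean(.data$eaf, .data$n),
      q_stat = sum(((.data$beta - .data$beta_c[1]) / .data$se)^2),
      n_studies = dplyr::n(),
      n = sum(.data$n),
      .groups = "drop"
    ) |>
    mutate(
      beta = .data$beta_c, se = .data$se_c,
      pvalue = 2 * pnorm(-abs(.data$beta / .data$se)),
      i2 = pmax(0, (.data$q_stat - (.data$n_studies - 1)) /
                  pmax(.data$q_stat, .Machine$double.eps)),
      monomorphic = FALSE
    ) |>
    select("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta", "se", "pvalue", "eaf", "n", "monomorphic",
           "n_studies", "q_stat", "i2") |>
    arrange(.data$chrom, .data$pos)
}
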