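#' Pipeline configuration
#'
#' Collects every threshold and size of the end-to-end synthetic analysis:
#' expression-panel simulation and model training, GWAS cohort simulation
#' with per-study split and fixed-effect meta-analysis, TWAS, gene-level MR,
#' bidirectional trait MR, and PheWAS.
#'
#' @param scenario A scenario name for [sim_scenario()] or a [sim_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_expression_samples Expression-panel size (default 305, the scale
#'   of a single-tissue reference panel).
#' @param n_studies GWAS cohort is split into this many equal studies and
#'   recombined by fixed-effect meta-analysis (default 2).
#' @param frameworks Prediction-model frameworks to train: subset of
#'   `c("elastic_net", "cross_tissue_group", "similarity_weighted")`.
#' @param p_threshold,r2_threshold,clump_window_bp Instrument selection for
#'   trait-level MR (defaults 5e-8, 0.01, 250 kb).
#' @param eqtl_p_threshold Exposure-association threshold for *gene-level*
#'   (cis-eQTL) instruments; looser than genome-wide (default 1e-5) because
#'   the exposure GWAS is a few-hundred-sample expression panel.
#' @param cis_window_bp Cis window for training and locus-restricted MR
#'   (default 1 Mb).
#' @param fdr_threshold TWAS significance threshold (default 0.10).
#' @param m_total BH family size for the TWAS (default 9952, the size of a
#'   full single-tissue transcriptome-wide scan: the simulated gene panel is
#'   treated as a window of that transcriptome, so significance labels carry
#'   the family-wise stringency of the full scan; set `NULL` to adjust over
#'   the genes tested only).
#' @param mr_methods Estimators for the MR stages.
#' @param n_boot Bootstrap replicates for bootstrap-based estimators.
#' @param n_pcs Expression principal components added to the covariate
#'   matrix before residualization (hidden-factor stand-ins; default 5).
#' @param second_trait Simulate a second trait caused by the first trait's
#'   genetic liability (`delta_ab`) with its own instruments (last gene),
#'   and run bidirectional MR (default TRUE).
#' @param delta_ab Causal effect of trait A's liability on trait B.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = "causal_gene", seed = 1L,
                       n_expression_samples = 305L, n_studies = 2L,
                       frameworks = "elastic_net",
                       p_threshold = 5e-8, r2_threshold = 0.01,
                       clump_window_bp = 250000, eqtl_p_threshold = 1e-5,
                       cis_window_bp = 1e6, fdr_threshold = 0.10,
                       m_total = 9952,
                       mr_methods = c("ivw", "wme", "egger", "het_penalized"),
                       n_boot = 200L, n_pcs = 5L,
                       second_trait = TRUE, delta_ab = 0.3) {
  stopifnot(p_threshold > 0, r2_threshold > 0, clump_window_bp > 0,
            cis_window_bp > 0, fdr_threshold > 0)
  sim <- if (inherits(scenario, "sim_config")) scenario else
    sim_scenario(scenario, seed = seed)
  structure(list(
    sim = sim, seed = as.integer(seed),
    n_expression_samples = as.integer(n_expression_samples),
    n_studies = as.integer(n_studies), frameworks = frameworks,
    p_threshold = p_threshold, r2_threshold = r2_threshold,
    clump_window_bp = clump_window_bp, eqtl_p_threshold = eqtl_p_threshold,
    cis_window_bp = cis_window_bp, fdr_threshold = fdr_threshold,
    m_total = m_total, mr_methods = mr_methods, n_boot = as.integer(n_boot),
    n_pcs = as.integer(n_pcs), second_trait = isTRUE(second_trait),
    delta_ab = delta_ab
  ), class = "run_config")
}

#' Run the end-to-end synthetic TWAS + MR pipeline
#'
#' Stages, in order: simulate an expression panel and train/select
#' prediction models; simulate a GWAS cohort, run per-study GWAS and combine
#' by fixed-effect meta-analysis; summary-statistics TWAS with BH
#' adjustment; gene-level MR (three pleiotropy-robust estimators) for the
#' TWAS-significant genes; bidirectional trait MR with locus restriction and
#' exclusion around the top gene; PheWAS of the top gene against a small
#' phenotype catalog (the traits plus permuted-null phenotypes). Every stage
#' writes a TSV into `out_dir` and appends per-stage record counts to
#' `log.txt`; a failure stops with the stage name, preserving earlier
#' outputs. Output is fully determined by the configuration and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return A list with elements `models`, `sumstats`, `twas`, `mr_gene`,
#'   `mr_bidirectional`, `phewas`, `log` (invisible file paths in
#'   `$paths`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  emit <- function(tbl, file) {
    if (!is.null(out_dir)) {
      readr::write_tsv(tbl, file.path(out_dir, file), progress = FALSE)
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(c(log_lines, sprintf("FAILED at stage: %s (%s)", name,
                                        conditionMessage(e))),
                   file.path(out_dir, "log.txt"))
      }
      abort(sprintf("Pipeline failed at stage '%s': %s", name,
                    conditionMessage(e)))
    })
  }
  cfg <- config$sim
  note("pipeline seed=%d scenario: %d genes, %d variants", config$seed,
       cfg$n_genes, cfg$n_variants)

  ## stage: expression panel + model training
  models <- stage("train", {
    cfg_expr <- do.call(sim_config, modifyList(
      unclass(cfg), list(n_samples = config$n_expression_samples,
                         seed = cfg$seed + 100L, causal_genes = cfg$causal_genes)))
    geno_expr <- simulate_genotypes(cfg_expr)
    expr <- simulate_expression(geno_expr, cfg_expr)
    covar <- cbind(expr$covariates,
                   expression_pcs(expr$expression$tissue1, config$n_pcs))
    resid <- lapply(expr$expression, regress_out_covariates, covariates = covar)
    tcfg <- training_config(cis_window_bp = config$cis_window_bp,
                            seed = cfg$seed + 200L)
    similarity <- matrix(0.8, cfg$n_tissues, cfg$n_tissues)
    diag(similarity) <- 1
    dimnames(similarity) <- list(names(resid), names(resid))
    selected <- vector("list", cfg$n_genes)
    eqtl_stats <- vector("list", cfg$n_genes)
    for (j in seq_len(cfg$n_genes)) {
      gene <- expr$genes[j, ]
      cand <- list()
      if ("elastic_net" %in% config$frameworks) {
        cand <- c(cand, list(train_elastic_net(
          resid$tissue1[, j], geno_expr$dosages, geno_expr$variants, gene,
          tcfg)))
      }
      if ("cross_tissue_group" %in% config$frameworks && cfg$n_tissues > 1) {
        xt <- train_cross_tissue(lapply(resid, function(m) m[, j]),
                                 geno_expr$dosages, geno_expr$variants, gene,
                                 tcfg)
        cand <- c(cand, list(xt$tissue1))
      }
      if ("similarity_weighted" %in% config$frameworks && cfg$n_tissues > 1) {
        cand <- c(cand, list(train_similarity_weighted(
          lapply(resid, function(m) m[, j]), geno_expr$dosages,
          geno_expr$variants, gene, similarity, tcfg)))
      }
      selected[[j]] <- select_best_model(cand)
      eqtl_stats[[j]] <- make_gwas_summary(geno_expr$dosages, resid$tissue1[, j],
                                           variants = geno_expr$variants)
    }
    names(selected) <- expr$genes$gene_id
    names(eqtl_stats) <- expr$genes$gene_id
    imputable <- purrr::compact(selected)
    note("train: %d/%d genes imputable", length(imputable), cfg$n_genes)
    emit(weights_table(imputable), "weights.tsv")
    list(selected = imputable, eqtl = eqtl_stats, genes = expr$genes)
  })

  ## stage: GWAS cohort, per-study GWAS, meta-analysis
  gwas <- stage("meta", {
    geno <- simulate_genotypes(cfg)
    expr_g <- simulate_expression(geno, cfg)
    pheno <- simulate_case_control(geno, expr_g, cfg)
    split_id <- rep(seq_len(config$n_studies), length.out = cfg$n_samples)
    studies <- map(seq_len(config$n_studies), function(s) {
      rows <- split_id == s
      make_gwas_summary(geno$dosages[rows, , drop = FALSE],
                        pheno$phenotype[rows], variants = geno$variants)
    })
    meta <- meta_fixed_effect(studies)
    note("meta: %d variants across %d studies", nrow(meta), length(studies))
    for (s in seq_along(studies)) {
      emit(studies[[s]], sprintf("sumstats_study%d.tsv", s))
    }
    emit(meta, "sumstats_meta.tsv")

    trait_b <- NULL
    if (config$second_trait) {
      # trait B: own instruments (last gene) + causal influence of trait A
      # liability (vertical path through A's causal genes)
      eta_a <- rowSums(cbind(0, expr_g$truth$genetic_value[, cfg$causal_genes,
                                                           drop = FALSE])) *
        cfg$gene_effect
      set.seed(cfg$seed + 3L)
      eta_b <- 0.5 * expr_g$truth$genetic_value[, cfg$n_genes] +
        config$delta_ab * eta_a
      alpha_b <- uniroot(function(a) mean(plogis(a + eta_b)) - 0.5,
                         c(-10, 10))$root
      y_b <- rbinom(cfg$n_samples, 1L, plogis(alpha_b + eta_b))
      trait_b <- make_gwas_summary(geno$dosages, y_b, variants = geno$variants)
      emit(trait_b, "sumstats_trait_b.tsv")
    }
    list(geno = geno, expr = expr_g, pheno = pheno, meta = meta,
         trait_b = trait_b)
  })
  panel <- ld_panel(gwas$geno)

  ## stage: TWAS
  twas <- stage("twas", {
    res <- twas_scan(models$selected, gwas$meta, panel,
                     m_total = config$m_total,
                     fdr_threshold = config$fdr_threshold)
    note("twas: %d genes tested, %d significant at FDR<%.2f", nrow(res),
         sum(res$significant), config$fdr_threshold)
    emit(res, "twas.tsv")
    res
  })

  ## stage: gene-level MR for TWAS-significant genes
  mr_gene <- stage("mr_gene", {
    sig <- filter(twas, .data$significant)
    rows <- map(sig$gene_id, function(gid) {
      gene <- models$genes[models$genes$gene_id == gid, ]
      iv <- build_instruments(models$eqtl[[gid]], gwas$meta, panel,
                              p_threshold = config$eqtl_p_threshold,
                              r2_threshold = config$r2_threshold,
                              window_bp = config$clump_window_bp,
                              locus = gene,
                              locus_window_bp = config$cis_window_bp,
                              exposure_id = gid)
      tryCatch(
        mutate(mr_all_methods(iv, methods = config$mr_methods,
                              n_boot = config$n_boot, seed = cfg$seed),
               gene_id = gid),
        mr_refusal = function(e) {
          note("mr_gene: %s refused (%d IVs)", gid, nrow(iv))
          NULL
        })
    })
    out <- list_rbind(purrr::compact(rows))
    note("mr_gene: %d genes estimated", length(unique(out$gene_id %||% character(0))))
    emit(out, "mr_gene.tsv")
    out
  })

  ## stage: bidirectional trait MR with locus restriction / exclusion
  mr_bidir <- stage("mr_bidirectional", {
    if (is.null(gwas$trait_b)) {
      tibble()
    } else {
      top_gene <- models$genes[models$genes$gene_id == twas$gene_id[1], ]
      runs <- list(
        all_snps = bidirectional_mr(
          gwas$meta, gwas$trait_b, panel,
          methods = setdiff(config$mr_methods, "het_penalized"),
          p_threshold = config$p_threshold,
          r2_threshold = config$r2_threshold,
          window_bp = config$clump_window_bp,
          labels = c("traitA", "traitB"),
          n_boot = config$n_boot, seed = cfg$seed),
        locus_restricted = bidirectional_mr(
          gwas$meta, gwas$trait_b, panel,
          methods = setdiff(config$mr_methods, "het_penalized"),
          p_threshold = config$p_threshold,
          r2_threshold = config$r2_threshold,
          window_bp = config$clump_window_bp,
          locus = top_gene, locus_window_bp = config$cis_window_bp,
          labels = c("traitA", "traitB"),
          n_boot = config$n_boot, seed = cfg$seed),
        locus_excluded = bidirectional_mr(
          gwas$meta, gwas$trait_b, panel,
          methods = setdiff(config$mr_methods, "het_penalized"),
          p_threshold = config$p_threshold,
          r2_threshold = config$r2_threshold,
          window_bp = config$clump_window_bp,
          exclude_locus = top_gene, locus_window_bp = config$cis_window_bp,
          labels = c("traitA", "traitB"),
          n_boot = config$n_boot, seed = cfg$seed))
      out <- list_rbind(imap(runs, function(x, nm) mutate(x, run = nm)))
      note("mr_bidirectional: %d estimates across %d runs", nrow(out),
           length(runs))
      emit(out, "mr_bidirectional.tsv")
      out
    }
  })

  ## stage: PheWAS of the top gene
  phewas <- stage("phewas", {
    if (nrow(twas) == 0) {
      tibble()
    } else {
      top_model <- models$selected[[twas$gene_id[1]]]
      set.seed(cfg$seed + 4L)
      null_gwas <- map(1:3, function(i) {
        make_gwas_summary(gwas$geno$dosages,
                          sample(gwas$pheno$phenotype),
                          variants = gwas$geno$variants)
      })
      cat_tbl <- phewas_catalog(
        phecode = c("157", "250.2", sprintf("null.%d", 1:3)),
        label = c("trait A", "trait B", sprintf("permuted %d", 1:3)),
        category = c("neoplasms", "endocrine", rep("null", 3)),
        gwas = c(list(gwas$meta),
                 list(gwas$trait_b %||% gwas$meta), null_gwas))
      res <- phewas_scan(top_model, cat_tbl, panel)
      note("phewas: %d phenotypes tested for %s", nrow(res),
           top_model$gene_id)
      emit(res, "phewas.tsv")
      res
    }
  })

  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "log.txt"))
    prov <- c(sprintf("twasmr version: %s",
                      as.character(utils::packageVersion("twasmr"))),
              sprintf("seed: %d", config$seed),
              paste0("config: ", deparse1(unclass(config)[
                setdiff(names(unclass(config)), "sim")])),
              paste0("sim_config: ", deparse1(unclass(cfg))))
    writeLines(prov, file.path(out_dir, "provenance.txt"))
  }
  invisible(list(models = models$selected, sumstats = gwas$meta,
                 twas = twas, mr_gene = mr_gene,
                 mr_bidirectional = mr_bidir, phewas = phewas,
                 log = log_lines,
                 paths = if (is.null(out_dir)) NULL else
                   list.files(out_dir, full.names = TRUE)))
}
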