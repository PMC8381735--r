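# End-to-end orchestration: ingest -> screen -> pair encoding -> signature
# selection -> ROC/cut-off -> evaluation, with a machine-readable run
# report. All thresholds default to the published screening values
# (r > 0.4, p < 0.001; |log2FC| > 1, FDR < 0.05; prevalence in (0.2, 0.8);
# univariate p < 0.05; 10-fold LASSO CV; 1/3/5-year horizons). A single
# master seed fans out to per-stage seeds so stages can be rerun
# independently.

#' Pipeline configuration
#'
#' @param input either the string `"synthetic"` (simulate via `sim`), or a
#'   named list of file paths: `expression`, `group_map`, `gene_catalog`,
#'   `immune_genes`, `clinical`, and optionally `immune_fractions`, `ic50`.
#' @param sim `sim_config` used when `input == "synthetic"`.
#' @param r_min,p_max co-expression screen thresholds.
#' @param lfc_min,fdr_max differential-expression thresholds.
#' @param pair_lo,pair_hi strict prevalence bounds for valid pairs.
#' @param univ_p univariate Cox retention p-value.
#' @param n_folds,n_repeats LASSO cross-validation protocol (the reference
#'   protocol runs 1000 repeats; smaller values bound runtime).
#' @param exhaustive_k exhaustive best-subset threshold for the AIC step.
#' @param horizons ROC horizons in days; the cut-off is chosen on the last
#'   (5-year) horizon.
#' @param seed master seed.
#' @param out_dir optional directory for stage TSV outputs and the JSON
#'   run report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic", sim = sim_config(),
                            r_min = 0.4, p_max = 0.001,
                            lfc_min = 1, fdr_max = 0.05,
                            pair_lo = 0.2, pair_hi = 0.8,
                            univ_p = 0.05, n_folds = 10L, n_repeats = 1000L,
                            exhaustive_k = 12L,
                            horizons = c(365, 1095, 1825),
                            seed = 1L, out_dir = NULL) {
  stopifnot(r_min >= -1, r_min <= 1, p_max > 0, p_max <= 1,
            lfc_min >= 0, fdr_max > 0, fdr_max <= 1,
            pair_lo < pair_hi, univ_p > 0, univ_p <= 1,
            n_folds >= 2, n_repeats >= 1, all(horizons > 0))
  structure(list(input = input, sim = sim, r_min = r_min, p_max = p_max,
                 lfc_min = lfc_min, fdr_max = fdr_max, pair_lo = pair_lo,
                 pair_hi = pair_hi, univ_p = univ_p,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 exhaustive_k = as.integer(exhaustive_k),
                 horizons = horizons, seed = as.integer(seed),
                 out_dir = out_dir), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [pipeline_config()]; keys under `sim:`
#' are passed to [sim_config()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  args <- y
  args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, args)
}

#' Run the full signature pipeline
#'
#' Executes ingest, the co-expression and differential-expression screens,
#' pair encoding with the prevalence filter, the univariate/LASSO/stepwise
#' Cox selection, the time-dependent ROC cut-off, and the downstream
#' evaluation, returning a run report with the stage counts (irlncRNAs,
#' DEirlncRNAs up/down, valid pairs, univariate-retained, LASSO-selected,
#' final signature size), the signature and cut-off, group sizes, and all
#' association tables.
#'
#' Pair prevalence is computed over the model-fitting samples (tumor
#' samples with valid clinical data); the screening stages use all
#' expression samples.
#'
#' @param config `pipeline_config`.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(nm) derive_seed(config$seed, nm)

  # ---- ingest -------------------------------------------------------------
  if (identical(config$input, "synthetic")) {
    sim <- config$sim
    sim$seed <- stage("syndata")
    cohort <- simulate_cohort(sim)
    expr <- cohort$expr; catalog <- cohort$catalog
    clinical_raw <- cohort$clinical
    immune_fractions <- cohort$immune_fractions
    ic50 <- cohort$ic50
    truth <- cohort$truth
  } else {
    paths <- config$input
    gm <- read_delim_auto(paths$group_map)
    expr <- read_expression(paths$expression,
                            stats::setNames(gm$group, gm$sample))
    catalog <- read_gene_catalog(paths$gene_catalog, paths$immune_genes)
    clinical_raw <- read_clinical(paths$clinical)
    immune_fractions <- if (!is.null(paths$immune_fractions))
      read_delim_auto(paths$immune_fractions) else NULL
    ic50 <- if (!is.null(paths$ic50)) read_delim_auto(paths$ic50) else NULL
    truth <- NULL
  }
  clinical <- filter_clinical(clinical_raw)

  # ---- screen -------------------------------------------------------------
  parts <- partition_genes(expr, catalog)
  if (nrow(parts$lnc) == 0) stop_validation("screen: no lncRNA genes in the catalog")
  coex <- coexpression_screen(parts$lnc, parts$immune,
                              r_min = config$r_min, p_max = config$p_max)
  ir_ids <- coex$gene[coex$passed]
  if (length(ir_ids) < 2)
    stop_validation("screen: fewer than 2 immune-related lncRNAs passed the co-expression screen")
  de <- differential_expression(parts$lnc[ir_ids, , drop = FALSE],
                                lfc_min = config$lfc_min,
                                fdr_max = config$fdr_max)
  de_ids <- de$gene[de$passed]
  if (length(de_ids) < 2)
    stop_validation("screen: fewer than 2 DEirlncRNAs; cannot form pairs")

  # ---- pair encoding ------------------------------------------------------
  fit_samples <- intersect(colnames(expr)[expr_group(expr) == "tumor"],
                           clinical$sample)
  pm_all <- encode_pairs(expr[de_ids, fit_samples, drop = FALSE])
  pm <- filter_pairs(pm_all, lo = config$pair_lo, hi = config$pair_hi)
  if (nrow(pm$C) == 0) stop_validation("pairenc: no pair survived the prevalence filter")

  # ---- signature selection ------------------------------------------------
  uni <- univariate_screen(pm, clinical, p_max = config$univ_p)
  pm_uni <- subset_pairs(pm, uni$pair)
  las <- lasso_cox_select(pm_uni, clinical, n_folds = config$n_folds,
                          n_repeats = config$n_repeats,
                          seed = stage("lasso"))
  pm_sel <- subset_pairs(pm, las$selected)
  final <- stepwise_aic(pm_sel, clinical, exhaustive_k = config$exhaustive_k)

  # ---- ROC / stratification ----------------------------------------------
  sig0 <- make_signature(final)
  risk <- risk_scores(sig0, pm)
  cl_fit <- clinical[match(names(risk), clinical$sample), ]
  rocs <- lapply(config$horizons, function(h)
    td_roc(risk, cl_fit$futime, cl_fit$fustat, h))
  names(rocs) <- paste0("t", config$horizons)
  cut <- choose_cutoff(rocs[[length(rocs)]])
  signature <- make_signature(final, cutoff = cut$cutoff)
  groups <- assign_groups(risk, cut$cutoff)
  roc_compare <- compare_clinical_roc(risk, clinical,
                                      t = config$horizons[length(config$horizons)])

  # ---- evaluation ---------------------------------------------------------
  lr <- logrank_test(cl_fit$futime, cl_fit$fustat, groups)
  km <- lapply(split(seq_along(groups), groups), function(ix)
    km_estimate(cl_fit$futime[ix], cl_fit$fustat[ix]))
  chisq <- lapply(c("stage", "T", "M", "N"), function(v) {
    tryCatch(chisq_association(groups, cl_fit[[v]]),
             error = function(e) NULL)
  })
  names(chisq) <- c("stage", "T", "M", "N")
  ranksum <- lapply(c("stage", "T", "M", "N"), function(v)
    tryCatch(ranksum_compare(risk, cl_fit[[v]], mode = "level_vs_rest"),
             error = function(e) NULL))
  names(ranksum) <- c("stage", "T", "M", "N")
  indep <- independence_cox(clinical, risk)
  imm_tab <- if (!is.null(immune_fractions))
    suppressWarnings(immune_correlation(risk, immune_fractions, group = groups))
    else NULL
  drug_tab <- if (!is.null(ic50))
    drug_sensitivity_compare(groups, ic50) else NULL

  report <- structure(list(
    counts = list(
      n_lnc = nrow(parts$lnc),
      n_irlnc = length(ir_ids),
      n_deirlnc = length(de_ids),
      n_deirlnc_up = sum(de$passed & de$direction == "up"),
      n_deirlnc_down = sum(de$passed & de$direction == "down"),
      n_pairs_total = nrow(pm_all$C),
      n_valid_pairs = nrow(pm$C),
      n_univariate = nrow(uni),
      n_lasso = length(las$selected),
      n_final = length(signature$pairs)),
    signature = signature,
    cutoff = cut$cutoff,
    risk = risk,
    groups = groups,
    group_sizes = as.list(table(groups)),
    auc = stats::setNames(vapply(rocs, `[[`, numeric(1), "auc"), names(rocs)),
    roc = rocs,
    roc_compare = roc_compare,
    logrank = lr,
    km = km,
    chisq = chisq,
    ranksum = ranksum,
    independence = indep,
    immune = imm_tab,
    drugs = drug_tab,
    screens = list(coexpression = coex, de = de),
    univariate = uni,
    lasso = las,
    truth = truth,
    seed = config$seed), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("lncRNA pair signature pipeline report\n")
  cat(sprintf("  funnel: %d lncRNA -> %d irlncRNA -> %d DEirlncRNA (%d up / %d down) -> %d valid pairs -> %d univariate -> %d LASSO -> %d final\n",
              x$counts$n_lnc, x$counts$n_irlnc, x$counts$n_deirlnc,
              x$counts$n_deirlnc_up, x$counts$n_deirlnc_down,
              x$counts$n_valid_pairs, x$counts$n_univariate,
              x$counts$n_lasso, x$counts$n_final))
  cat(sprintf("  cutoff = %.4f; groups: high = %d, low = %d\n",
              x$cutoff, x$group_sizes$high, x$group_sizes$low))
  cat(sprintf("  AUC: %s\n",
              paste(sprintf("%s = %.3f", names(x$auc), x$auc), collapse = ", ")))
  cat(sprintf("  log-rank: chi-square = %.3f, p = %.3g\n",
              x$logrank$statistic, x$logrank$p))
  invisible(x)
}

# Stage TSV outputs plus a JSON run report.
write_report <- function(report, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  wt <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(report$screens$coexpression, "coexpression_screen.tsv")
  wt(report$screens$de, "differential_expression.tsv")
  wt(report$univariate, "univariate_cox.tsv")
  if (!is.null(report$lasso$cv)) wt(report$lasso$cv, "lasso_cv.tsv")
  wt(data.frame(pair = report$signature$pairs,
                weight = report$signature$weights), "signature.tsv")
  wt(data.frame(sample = names(report$risk), risk = unname(report$risk),
                group = as.character(report$groups)), "risk_scores.tsv")
  wt(report$roc[[length(report$roc)]]$curve, "roc_5yr_curve.tsv")
  wt(report$roc_compare, "roc_auc_compare.tsv")
  wt(report$independence$univariate, "cox_univariate_clinical.tsv")
  wt(report$independence$multivariate, "cox_multivariate_clinical.tsv")
  if (!is.null(report$immune)) wt(report$immune, "immune_correlation.tsv")
  if (!is.null(report$drugs)) wt(report$drugs, "drug_sensitivity.tsv")
  jsonlite::write_json(list(
    seed = report$seed,
    counts = report$counts,
    cutoff = report$cutoff,
    group_sizes = report$group_sizes,
    auc = as.list(report$auc),
    logrank_p = report$logrank$p,
    signature = list(pairs = report$signature$pairs,
                     weights = report$signature$weights)),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(NULL)
}
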