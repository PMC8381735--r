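# Synthetic cohort generator with planted ground truth.
#
# Expression model: per-gene Gaussian log2 values with a single shared
# latent immune-activity factor per sample; FPKM = 2^x. Immune genes and a
# chosen set of lncRNAs load on the factor (planting the co-expression
# signal); a subset of lncRNAs receives a tumor-vs-normal mean shift
# (planting differential expression). Survival for tumor samples follows an
# exponential proportional-hazards model whose linear predictor eta is a
# weighted sum of binary pair indicators over planted prognostic pairs,
# computed with the same encoding rule the pipeline uses. Clinical stage,
# immune-infiltration fractions and drug IC50 values are generated from eta
# so downstream association tests have planted signal.

#' Synthetic-cohort configuration
#'
#' Defaults describe the reference simulation regime: a colorectal-like
#' cohort of 600 tumor and 40 normal samples, 200 lncRNAs of which 60 are
#' immune-co-expressed and 40 differentially expressed, 100 immune
#' protein-coding genes, and 4 planted prognostic pairs with log-hazard
#' weights of magnitude 0.8-1.2. The baseline hazard of 3.8e-4 per day
#' gives roughly 50% baseline survival at 5 years; target censoring is 50%
#' with a 10-year administrative horizon.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_lnc,n_imm counts of lncRNA and immune protein-coding genes.
#' @param n_coexpr lncRNAs loaded on the latent immune factor.
#' @param n_de lncRNAs with a planted tumor-vs-normal shift (drawn from the
#'   co-expressed set first, so they survive both screens).
#' @param n_true_pairs planted prognostic pairs (disjoint genes, indicator
#'   prevalence inside the validity window by construction).
#' @param beta_range interval for the magnitude of true log-hazard weights;
#'   signs are random. `c(0, 0)` plants no survival signal.
#' @param baseline_hazard exponential baseline rate per day.
#' @param censor_rate target censoring fraction in \[0, 1).
#' @param admin_horizon administrative censoring horizon, days.
#' @param de_lfc planted log2 shift magnitude for DE lncRNAs.
#' @param prob_up probability that a planted DE shift is upward.
#' @param clin_strength effect of eta on the advanced-stage odds.
#' @param immune_strength,drug_strength effect of eta on immune fractions
#'   (logit scale) and on IC50 (negative direction: high risk, lower IC50).
#' @param n_celltypes immune cell-type columns.
#' @param drugs drug names for the IC50 table; the first receives no
#'   planted effect (a built-in negative control).
#' @param n_other non-immune protein-coding genes (catalog padding).
#' @param seed integer driving all randomness.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 600L, n_normal = 40L, n_lnc = 200L,
                       n_imm = 100L, n_coexpr = 60L, n_de = 40L,
                       n_true_pairs = 4L, beta_range = c(0.8, 1.2),
                       baseline_hazard = 3.8e-4, censor_rate = 0.5,
                       admin_horizon = 3650, de_lfc = 2, prob_up = 0.85,
                       clin_strength = 0.8, immune_strength = 0.6,
                       drug_strength = 0.8, n_celltypes = 10L,
                       drugs = c("Gemcitabine", "Rapamycin", "Imatinib",
                                 "Lenalidomide", "Shikonin"),
                       n_other = 10L, seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_lnc = as.integer(n_lnc), n_imm = as.integer(n_imm),
              n_coexpr = as.integer(n_coexpr), n_de = as.integer(n_de),
              n_true_pairs = as.integer(n_true_pairs),
              beta_range = as.numeric(beta_range),
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              admin_horizon = admin_horizon, de_lfc = de_lfc,
              prob_up = prob_up, clin_strength = clin_strength,
              immune_strength = immune_strength, drug_strength = drug_strength,
              n_celltypes = as.integer(n_celltypes), drugs = drugs,
              n_other = as.integer(n_other), seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_tumor, n_normal, n_lnc, n_imm) <= 0))
      stop_validation("all sample/gene counts must be positive")
    if (n_de > n_lnc || n_coexpr > n_lnc)
      stop_validation("n_de and n_coexpr cannot exceed n_lnc")
    if (censor_rate < 0 || censor_rate >= 1)
      stop_validation("censor_rate must lie in [0, 1)")
    if (length(beta_range) != 2 || beta_range[1] > beta_range[2] ||
        any(beta_range < 0))
      stop_validation("beta_range must be a non-negative interval [lo, hi]")
    n_elig <- min(n_de, n_coexpr)
    if (n_true_pairs > n_elig %/% 2)
      stop_validation(
        "n_true_pairs = %d exceeds the %d disjoint pairs available among the %d DE-and-co-expressed lncRNAs",
        n_true_pairs, n_elig %/% 2, n_elig)
    if (baseline_hazard <= 0 || admin_horizon <= 0)
      stop_validation("baseline_hazard and admin_horizon must be positive")
  })
  structure(cfg, class = "sim_config")
}

# censoring rate solving: exponential censoring at rate cr plus the
# administrative horizon; P(event_i) = lam_i/(lam_i+cr) (1 - e^-(lam_i+cr)h)
calibrate_censoring <- function(lam, censor_rate, horizon) {
  p_event <- function(cr) {
    tot <- lam + cr
    mean(lam / tot * (1 - exp(-tot * horizon)))
  }
  target <- 1 - censor_rate
  if (p_event(1e-12) <= target) {
    if (p_event(1e-12) < target - 0.05)
      warning("administrative horizon alone censors more than the target; censor_rate not attainable",
              call. = FALSE)
    return(0)
  }
  stats::uniroot(function(cr) p_event(cr) - target,
                 lower = 1e-12, upper = 10, tol = 1e-12)$root
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' @param config `sim_config`.
#' @param truth optional `GroundTruth` from a previous call: reuses the
#'   planted structure (gene means, factor loadings, DE shifts, true pairs
#'   and weights, clinical/immune/drug effect parameters) and draws only
#'   new samples — an independent test cohort for a fitted signature.
#' @return list of class `sim_cohort`: `expr` (`expr_matrix`, all genes),
#'   `catalog` (gene catalog data frame), `clinical` (tumor samples),
#'   `immune_fractions`, `ic50`, `truth` (class `ground_truth`: planted DE
#'   genes, co-expressed genes, true pairs with weights, per-tumor-sample
#'   linear predictor `eta`, effect parameters, and the structural `params`
#'   record).
#' @export
simulate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, simulate_cohort_impl(config, truth))
}

simulate_cohort_impl <- function(cfg, truth) {
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lnc))
  imm_ids <- sprintf("IMM%04d", seq_len(cfg$n_imm))
  oth_ids <- if (cfg$n_other > 0) sprintf("PCG%04d", seq_len(cfg$n_other)) else character()
  genes <- c(lnc_ids, imm_ids, oth_ids)

  if (is.null(truth)) {
    coexpr_ids <- lnc_ids[seq_len(cfg$n_coexpr)]
    n_from_coexpr <- min(cfg$n_de, cfg$n_coexpr)
    de_ids <- c(coexpr_ids[seq_len(n_from_coexpr)],
                setdiff(lnc_ids, coexpr_ids)[seq_len(cfg$n_de - n_from_coexpr)])
    de_ids <- de_ids[!is.na(de_ids)]
    mu <- stats::setNames(stats::runif(length(genes), 2, 6), genes)
    loading <- stats::setNames(numeric(length(genes)), genes)
    loading[imm_ids] <- stats::runif(cfg$n_imm, 0.9, 1.1)
    loading[coexpr_ids] <- stats::runif(cfg$n_coexpr, 0.9, 1.1)
    noise_sd <- stats::setNames(ifelse(loading > 0, 0.8, 1.0), genes)
    de_shift <- stats::setNames(numeric(length(genes)), genes)
    de_shift[de_ids] <- cfg$de_lfc *
      ifelse(stats::runif(length(de_ids)) < cfg$prob_up, 1, -1)
    anchors <- stats::setNames(sample(imm_ids, cfg$n_coexpr, replace = TRUE),
                               coexpr_ids)
    cell_names <- sprintf("CellType%02d", seq_len(cfg$n_celltypes))
    cell_a <- stats::setNames(stats::qlogis(stats::runif(cfg$n_celltypes, 0.05, 0.3)),
                              cell_names)
    n_pos <- ceiling(cfg$n_celltypes * 0.6)
    cell_b <- stats::setNames(
      cfg$immune_strength * rep(c(1, -1), c(n_pos, cfg$n_celltypes - n_pos)),
      cell_names)
    drug_c <- stats::setNames(stats::runif(length(cfg$drugs), 2, 6), cfg$drugs)
    drug_d <- stats::setNames(rep(cfg$drug_strength, length(cfg$drugs)), cfg$drugs)
    drug_d[1L] <- 0   # negative-control drug
    stage_cuts <- stats::qlogis(c(0.17, 0.55, 0.85))
    t_cuts <- stats::qlogis(c(0.03, 0.20, 0.88))
    n_cuts <- stats::qlogis(c(0.57, 0.81))
    m_cuts <- stats::qlogis(0.86)
    params <- list(mu = mu, loading = loading, noise_sd = noise_sd,
                   de_shift = de_shift, anchors = anchors,
                   cell_a = cell_a, cell_b = cell_b,
                   drug_c = drug_c, drug_d = drug_d,
                   stage_cuts = stage_cuts, t_cuts = t_cuts,
                   n_cuts = n_cuts, m_cuts = m_cuts,
                   coexpr_ids = coexpr_ids, de_ids = de_ids,
                   true_pairs = NULL)   # filled after pair selection
  } else {
    params <- truth$params
    mu <- params$mu; loading <- params$loading; noise_sd <- params$noise_sd
    de_shift <- params$de_shift
    coexpr_ids <- params$coexpr_ids; de_ids <- params$de_ids
    cell_names <- names(params$cell_a)
  }

  tum_ids <- sprintf("T%04d", seq_len(cfg$n_tumor))
  nor_ids <- sprintf("N%04d", seq_len(cfg$n_normal))
  samples <- c(tum_ids, nor_ids)
  is_tumor <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_normal))
  z <- stats::rnorm(length(samples))
  eps <- matrix(stats::rnorm(length(genes) * length(samples)),
                nrow = length(genes))
  x <- mu[genes] + outer(loading[genes], z) + noise_sd[genes] * eps +
    outer(de_shift[genes], as.numeric(is_tumor))
  fpkm <- 2^x
  dimnames(fpkm) <- list(genes, samples)
  group <- stats::setNames(ifelse(is_tumor, "tumor", "normal"), samples)
  expr <- make_expr_matrix(fpkm, group)

  # planted prognostic pairs among DE-and-co-expressed lncRNAs, chosen so
  # the indicator prevalence over tumor samples sits strictly inside the
  # validity window, genes disjoint across pairs
  elig <- intersect(de_ids, coexpr_ids)
  if (is.null(truth)) {
    true_pairs <- select_true_pairs(expr, elig, tum_ids, cfg)
    params$true_pairs <- true_pairs
  } else {
    true_pairs <- params$true_pairs
  }

  # eta from the pair indicators, computed with the pipeline's own encoder
  eta <- stats::setNames(numeric(cfg$n_tumor), tum_ids)
  if (nrow(true_pairs) > 0 && any(true_pairs$beta != 0)) {
    for (k in seq_len(nrow(true_pairs))) {
      sub <- unclass(expr)[c(true_pairs$geneA[k], true_pairs$geneB[k]),
                           tum_ids, drop = FALSE]
      Ck <- encode_pairs(make_expr_matrix(sub, group[tum_ids]))$C[1L, ]
      eta <- eta + true_pairs$beta[k] * Ck
    }
  } else if (nrow(true_pairs) > 0) {
    eta[] <- 0
  }

  lam <- cfg$baseline_hazard * exp(eta)
  t_event <- stats::rexp(cfg$n_tumor, lam)
  cr <- calibrate_censoring(lam, cfg$censor_rate, cfg$admin_horizon)
  t_cens <- if (cr > 0) pmin(stats::rexp(cfg$n_tumor, cr), cfg$admin_horizon)
            else rep(cfg$admin_horizon, cfg$n_tumor)
  futime <- pmin(t_event, t_cens)
  fustat <- as.integer(t_event <= t_cens)

  ord_cat <- function(cuts, labels) {
    u <- cfg$clin_strength * eta + stats::rlogis(cfg$n_tumor)
    cut(u, breaks = c(-Inf, cuts, Inf), labels = labels)
  }
  clinical <- data.frame(
    sample = tum_ids,
    futime = futime,
    fustat = fustat,
    age = pmin(pmax(round(stats::rnorm(cfg$n_tumor, 65, 10)), 30), 90),
    stage = ord_cat(params$stage_cuts, c("I", "II", "III", "IV")),
    T = ord_cat(params$t_cuts, c("T1", "T2", "T3", "T4")),
    M = ord_cat(params$m_cuts, c("M0", "M1")),
    N = ord_cat(params$n_cuts, c("N0", "N1", "N2")),
    stringsAsFactors = FALSE)

  fr <- vapply(cell_names, function(ct) {
    stats::plogis(params$cell_a[ct] + params$cell_b[ct] * eta +
                    stats::rnorm(cfg$n_tumor, 0, 0.5))
  }, numeric(cfg$n_tumor))
  immune_fractions <- data.frame(sample = tum_ids, fr, check.names = FALSE)

  ic <- vapply(names(params$drug_c), function(dr) {
    params$drug_c[dr] - params$drug_d[dr] * eta +
      stats::rnorm(cfg$n_tumor, 0, 0.5)
  }, numeric(cfg$n_tumor))
  ic50 <- data.frame(sample = tum_ids, ic, check.names = FALSE)

  catalog <- data.frame(
    gene_id = genes,
    biotype = c(rep("lncRNA", cfg$n_lnc), rep("protein_coding", cfg$n_imm),
                rep("protein_coding", cfg$n_other)),
    immune = c(rep(FALSE, cfg$n_lnc), rep(TRUE, cfg$n_imm),
               rep(FALSE, cfg$n_other)),
    stringsAsFactors = FALSE)

  gt <- structure(list(
    de_gene_ids = de_ids,
    coexpr_gene_ids = coexpr_ids,
    true_pairs = true_pairs,
    true_linear_predictor = eta,
    cell_effects = params$cell_b,
    drug_effects = params$drug_d,
    params = params), class = "ground_truth")

  structure(list(expr = expr, catalog = catalog, clinical = clinical,
                 immune_fractions = immune_fractions, ic50 = ic50,
                 truth = gt, config = cfg), class = "sim_cohort")
}

select_true_pairs <- function(expr, elig, tum_ids, cfg) {
  if (cfg$n_true_pairs == 0)
    return(data.frame(geneA = character(), geneB = character(),
                      beta = numeric()))
  sub <- unclass(expr)[elig, tum_ids, drop = FALSE]
  pm <- encode_pairs(make_expr_matrix(sub, rep("tumor", length(tum_ids))))
  ok <- pm$prevalence > 0.2 & pm$prevalence < 0.8
  cand <- pm$pairs[ok, , drop = FALSE]
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  chosen <- list(); used <- character()
  for (i in seq_len(nrow(cand))) {
    if (cand$geneA[i] %in% used || cand$geneB[i] %in% used) next
    chosen[[length(chosen) + 1L]] <- cand[i, ]
    used <- c(used, cand$geneA[i], cand$geneB[i])
    if (length(chosen) == cfg$n_true_pairs) break
  }
  if (length(chosen) < cfg$n_true_pairs)
    stop_validation("could not plant %d disjoint valid pairs (only %d found)",
                    cfg$n_true_pairs, length(chosen))
  out <- do.call(rbind, chosen)
  mag <- stats::runif(cfg$n_true_pairs, cfg$beta_range[1], cfg$beta_range[2])
  sgn <- sample(c(-1, 1), cfg$n_true_pairs, replace = TRUE)
  out$beta <- mag * sgn
  rownames(out) <- NULL
  out[, c("geneA", "geneB", "beta")]
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d samples; %d planted DE lncRNAs, %d true pairs\n",
              nrow(x$expr), ncol(x$expr), length(x$truth$de_gene_ids),
              nrow(x$truth$true_pairs)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of delimited text files
#'
#' Produces the exact dialects the ingest module reads: `expression.tsv`
#' (genes x samples), `gene_catalog.tsv`, `immune_genes.txt`,
#' `group_map.tsv`, `clinical.tsv`, `immune_fractions.tsv`, `ic50.tsv`,
#' plus the ground truth as `ground_truth.json`.
#'
#' @param cohort `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!is.character(dir) || length(dir) != 1L || !nzchar(dir))
    stop("output directory path must be a non-empty string", call. = FALSE)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  wt <- function(df, file, row_names_col = NULL) {
    path <- file.path(dir, file)
    if (!is.null(row_names_col)) {
      df <- data.frame(stats::setNames(list(rownames(df)), row_names_col),
                       as.data.frame(df), check.names = FALSE)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    wt(unclass(cohort$expr), "expression.tsv", row_names_col = "gene_id"),
    wt(cohort$catalog[, c("gene_id", "biotype")], "gene_catalog.tsv"),
    {
      p <- file.path(dir, "immune_genes.txt")
      writeLines(cohort$catalog$gene_id[cohort$catalog$immune], p)
      p
    },
    wt(data.frame(sample = colnames(cohort$expr),
                  group = as.character(expr_group(cohort$expr))),
       "group_map.tsv"),
    wt(cohort$clinical, "clinical.tsv"),
    wt(cohort$immune_fractions, "immune_fractions.tsv"),
    wt(cohort$ic50, "ic50.tsv"),
    {
      p <- file.path(dir, "ground_truth.json")
      gt <- cohort$truth
      jsonlite::write_json(list(
        de_gene_ids = gt$de_gene_ids,
        coexpr_gene_ids = gt$coexpr_gene_ids,
        true_pairs = gt$true_pairs,
        true_linear_predictor = as.list(gt$true_linear_predictor),
        cell_effects = as.list(gt$cell_effects),
        drug_effects = as.list(gt$drug_effects)
      ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      p
    })
  invisible(files)
}

#' Read a written cohort back from disk
#'
#' Counterpart of [write_cohort()]; the expression matrix round-trips
#' through the ingest reader.
#'
#' @param dir directory written by [write_cohort()].
#' @return list with `expr`, `catalog`, `clinical`, `immune_fractions`,
#'   `ic50`, `truth` (ground truth re-read from JSON; `params` is not
#'   serialized).
#' @export
read_cohort <- function(dir) {
  gm <- read_delim_auto(file.path(dir, "group_map.tsv"))
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          stats::setNames(gm$group, gm$sample))
  catalog <- read_gene_catalog(file.path(dir, "gene_catalog.tsv"),
                               file.path(dir, "immune_genes.txt"))
  clinical <- read_clinical(file.path(dir, "clinical.tsv"))
  fr <- read_delim_auto(file.path(dir, "immune_fractions.tsv"))
  ic <- read_delim_auto(file.path(dir, "ic50.tsv"))
  gt_raw <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  truth <- structure(list(
    de_gene_ids = gt_raw$de_gene_ids,
    coexpr_gene_ids = gt_raw$coexpr_gene_ids,
    true_pairs = as.data.frame(gt_raw$true_pairs),
    true_linear_predictor = unlist(gt_raw$true_linear_predictor),
    cell_effects = unlist(gt_raw$cell_effects),
    drug_effects = unlist(gt_raw$drug_effects),
    params = NULL), class = "ground_truth")
  list(expr = expr, catalog = catalog, clinical = clinical,
       immune_fractions = fr, ic50 = ic, truth = truth)
}
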