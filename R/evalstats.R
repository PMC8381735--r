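# Downstream evaluation of the risk stratification: Kaplan-Meier curves,
# log-rank testing, clinicopathological association tests, independence Cox
# models, immune-infiltration correlation and drug-IC50 comparisons.
#
# Every association result carries (statistic, p, n, direction/effect) —
# no bare p-values.

#' Kaplan-Meier product-limit estimate
#'
#' Events precede censorings at equal times (both remain at risk at that
#' time). The curve is defined at the observed event times.
#'
#' @param time positive follow-up times.
#' @param status 0/1 event indicator.
#' @return data frame: `time` (unique event times), `n_risk`, `n_event`,
#'   `surv` (product-limit survival). With all observations censored the
#'   frame is empty (survival constant at 1).
#' @export
km_estimate <- function(time, status) {
  if (!length(time)) stop_validation("empty survival input")
  if (any(time <= 0)) stop_validation("times must be positive")
  if (!is_binary(status)) stop_validation("status must be 0/1")
  ev_t <- sort(unique(time[status == 1]))
  n_risk <- vapply(ev_t, function(tt) sum(time >= tt), numeric(1))
  n_event <- vapply(ev_t, function(tt) sum(time == tt & status == 1), numeric(1))
  data.frame(time = ev_t, n_risk = n_risk, n_event = n_event,
             surv = cumprod(1 - n_event / n_risk))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on 1 degree of freedom with hypergeometric
#' variance, two-sided.
#'
#' @param time,status survival outcome.
#' @param group factor with exactly two levels.
#' @return list (class `assoc_result`): `test = "logrank"`, `statistic`,
#'   `df`, `p`, `n` per group, `observed`/`expected` events per group, and
#'   `direction` (group with the worse observed/expected ratio).
#' @export
logrank_test <- function(time, status, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop_validation("log-rank test requires exactly 2 groups")
  g1 <- levels(group)[1L]
  ev_t <- sort(unique(time[status == 1]))
  if (!length(ev_t)) stop_validation("no events observed")
  o1 <- e1 <- v <- 0
  for (tt in ev_t) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & status == 1)
    d1 <- sum(time == tt & status == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  obs <- c(o1, sum(status) - o1)
  expd <- c(e1, sum(status) - e1)
  names(obs) <- names(expd) <- levels(group)
  worse <- levels(group)[which.max(obs / pmax(expd, .Machine$double.eps))]
  structure(list(test = "logrank", statistic = stat, df = 1L, p = p,
                 n = table(group), observed = obs, expected = expd,
                 direction = worse), class = "assoc_result")
}

#' Chi-square association between risk group and a clinical category
#'
#' Pearson chi-square without continuity correction; a warning is issued
#' when any expected count is below 5.
#'
#' @param group risk-group labels.
#' @param category clinical category labels (aligned).
#' @return `assoc_result` list: `statistic`, `df`, `p`, `n`, `table`.
#' @export
chisq_association <- function(group, category) {
  tab <- table(factor(group), factor(category))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop_validation("degenerate contingency table (a zero margin)")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 5))
    warning("expected count below 5 in the contingency table; chi-square approximation may be poor",
            call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(test = "chisq", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 n = sum(tab), table = tab), class = "assoc_result")
}

#' Rank-sum comparison of a continuous value between groups
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test with tie-corrected
#' normal approximation and continuity correction, two-sided. For
#' multi-level groupings, comparisons run either pairwise between levels or
#' each level against the rest.
#'
#' @param values numeric vector (e.g. risk scores or IC50).
#' @param group factor; two or more levels.
#' @param mode for > 2 levels: `"pairwise"` or `"level_vs_rest"`.
#' @return for two groups an `assoc_result` (`statistic` = Mann-Whitney U
#'   of the first level, `p`, `n`, group `medians`, `direction`); for more,
#'   a data frame of such comparisons.
#' @export
ranksum_compare <- function(values, group, mode = c("pairwise", "level_vs_rest")) {
  mode <- match.arg(mode)
  group <- droplevels(factor(group))
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop_validation("each group must be non-empty and at least 2 groups supplied")
  two_group <- function(v1, v2, lab1, lab2) {
    wt <- suppressWarnings(stats::wilcox.test(v1, v2, exact = FALSE,
                                              correct = TRUE))
    m1 <- stats::median(v1); m2 <- stats::median(v2)
    structure(list(test = "ranksum", statistic = unname(wt$statistic),
                   p = wt$p.value, n = c(length(v1), length(v2)),
                   medians = stats::setNames(c(m1, m2), c(lab1, lab2)),
                   direction = if (m1 < m2) sprintf("%s < %s", lab1, lab2)
                               else if (m1 > m2) sprintf("%s > %s", lab1, lab2)
                               else "equal medians"),
              class = "assoc_result")
  }
  lv <- levels(group)
  if (length(lv) == 2)
    return(two_group(values[group == lv[1]], values[group == lv[2]],
                     lv[1], lv[2]))
  if (mode == "pairwise") {
    cmb <- utils::combn(lv, 2L, simplify = FALSE)
    rows <- lapply(cmb, function(pr) {
      r <- two_group(values[group == pr[1]], values[group == pr[2]],
                     pr[1], pr[2])
      data.frame(level_a = pr[1], level_b = pr[2], statistic = r$statistic,
                 p = r$p, direction = r$direction)
    })
  } else {
    rows <- lapply(lv, function(l) {
      r <- two_group(values[group == l], values[group != l], l, "rest")
      data.frame(level_a = l, level_b = "rest", statistic = r$statistic,
                 p = r$p, direction = r$direction)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate and multivariate Cox models for prognostic independence
#'
#' Fits one univariate Cox model per covariate (ordinally coded clinical
#' variables plus the continuous risk score) and one joint multivariate
#' model, using the package's partial-likelihood engine. Collinear
#' covariates are flagged and the later-listed one is removed from the
#' multivariate fit.
#'
#' @param clinical clinical table with `sample`, `futime`, `fustat` and
#'   staging columns.
#' @param risk named risk-score vector (matched on `sample`).
#' @return list of two forest-plot-ready data frames (`univariate`,
#'   `multivariate`) with columns `covariate`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`.
#' @export
independence_cox <- function(clinical, risk) {
  cl <- clinical[match(names(risk), clinical$sample), , drop = FALSE]
  covs <- encode_clinical_ordinal(cl)
  covs$risk_score <- unname(risk)
  covs <- covs[, vapply(covs, function(v) stats::sd(v, na.rm = TRUE) > 0,
                        logical(1)), drop = FALSE]
  ok <- stats::complete.cases(covs)
  covs <- covs[ok, , drop = FALSE]
  tt <- cl$futime[ok]; ss <- cl$fustat[ok]
  row_of <- function(fit, nm) data.frame(
    covariate = nm, hr = unname(fit$hr[nm]), ci_lower = unname(fit$ci_lower[nm]),
    ci_upper = unname(fit$ci_upper[nm]), p = unname(fit$p[nm]))
  uni <- do.call(rbind, lapply(names(covs), function(nm) {
    f <- suppressWarnings(fit_cox(tt, ss, as.matrix(stats::setNames(covs[nm], nm))))
    row_of(f, nm)
  }))
  X <- as.matrix(covs)
  qr_x <- qr(cbind(1, scale(X)))
  if (qr_x$rank < ncol(X) + 1) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)] - 1L
    keep <- keep[keep >= 1L]
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    warning(sprintf("collinear covariate(s) dropped from multivariate fit: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  mv_fit <- suppressWarnings(fit_cox(tt, ss, X))
  mv <- do.call(rbind, lapply(colnames(X), function(nm) row_of(mv_fit, nm)))
  list(univariate = uni, multivariate = mv)
}

# Spearman rho with average ranks; two-sided p by t approximation
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Correlation of immune-infiltration scores with the risk score
#'
#' Per cell-type column: Spearman correlation (average ranks, two-sided
#' t-approximation p) against the risk score, plus a rank-sum comparison of
#' the cell-type scores between the high and low risk groups. Constant
#' columns are skipped with a warning.
#'
#' @param risk named risk-score vector.
#' @param fractions data frame or matrix, samples in rows (rownames or a
#'   `sample` column), immune cell types in columns.
#' @param group optional risk-group factor for the high/low comparison.
#' @param p_max significance filter recorded in the `passed` column,
#'   default 0.05.
#' @return data frame sorted by `rho`: `cell_type`, `rho`, `p`, `n`,
#'   `passed`, and when `group` is given `p_ranksum`, `direction`.
#' @export
immune_correlation <- function(risk, fractions, group = NULL, p_max = 0.05) {
  fractions <- as.data.frame(fractions)
  if ("sample" %in% names(fractions)) {
    rownames(fractions) <- fractions$sample
    fractions$sample <- NULL
  }
  shared <- intersect(names(risk), rownames(fractions))
  if (length(shared) < 3) stop_validation("fewer than 3 shared samples")
  fr <- fractions[shared, , drop = FALSE]
  rk <- risk[shared]
  if (!is.null(group)) group <- group[shared]
  rows <- lapply(names(fr), function(ct) {
    v <- fr[[ct]]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      warning(sprintf("constant immune column '%s' skipped", ct), call. = FALSE)
      return(NULL)
    }
    sp <- spearman_test(rk, v)
    row <- data.frame(cell_type = ct, rho = sp$rho, p = sp$p, n = sp$n,
                      passed = !is.na(sp$p) & sp$p < p_max)
    if (!is.null(group)) {
      rs <- ranksum_compare(v, group)
      row$p_ranksum <- rs$p
      row$direction <- rs$direction
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rho), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drug-sensitivity (IC50) comparison between risk groups
#'
#' Per drug: rank-sum test of IC50 between high and low risk groups, with
#' the direction indicating which group has the lower median IC50 (greater
#' sensitivity).
#'
#' @param group risk-group factor named by sample.
#' @param ic50 data frame/matrix of IC50 values, samples in rows (rownames
#'   or `sample` column), drugs in columns.
#' @return data frame: `drug`, `statistic`, `p`, `median_high`,
#'   `median_low`, `direction`.
#' @export
drug_sensitivity_compare <- function(group, ic50) {
  ic50 <- as.data.frame(ic50)
  if ("sample" %in% names(ic50)) {
    rownames(ic50) <- ic50$sample
    ic50$sample <- NULL
  }
  shared <- intersect(names(group), rownames(ic50))
  g <- droplevels(factor(group[shared]))
  if (nlevels(g) != 2 || any(table(g) < 2))
    stop_validation("both risk groups need at least 2 samples with IC50 data")
  rows <- lapply(names(ic50), function(dr) {
    v <- ic50[shared, dr]
    ok <- !is.na(v)
    if (!any(ok)) return(NULL)
    if (any(table(g[ok]) < 2))
      stop_validation("drug '%s': a risk group has fewer than 2 IC50 values", dr)
    r <- ranksum_compare(v[ok], g[ok])
    data.frame(drug = dr, statistic = r$statistic, p = r$p,
               median_high = unname(r$medians["high"]),
               median_low = unname(r$medians["low"]),
               direction = r$direction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g\n", x$test,
              x$statistic, x$p))
  if (!is.null(x$direction)) cat("direction:", x$direction, "\n")
  invisible(x)
}
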