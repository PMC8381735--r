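# Screening of immune-related lncRNAs (co-expression with immune genes)
# and of differentially expressed irlncRNAs (tumor vs normal).
#
# Both screens work on log2(FPKM + 1). The correlation cut is signed
# (r > r_min, not |r|); the differential-expression test is a two-group
# Wilcoxon rank-sum with Benjamini-Hochberg control over the tested set.

log2p1 <- function(x) log2(x + 1)

# two-sided p for Pearson r via t = r * sqrt((n-2)/(1-r^2))
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p
}

#' Co-expression screen for immune-related lncRNAs
#'
#' For every lncRNA, computes the Pearson correlation (on log2(FPKM+1))
#' against every immune gene across the shared samples. A lncRNA passes if
#' any immune partner satisfies `r > r_min` and `p < p_max` (signed r; the
#' p-value is the two-sided t-approximation with n-2 degrees of freedom).
#'
#' @param lnc_expr,immune_expr `expr_matrix` objects over the identical
#'   sample set and order.
#' @param r_min minimum (signed) correlation, default 0.4.
#' @param p_max maximum correlation p-value, default 0.001.
#' @return data frame with one row per lncRNA: `gene`, `best_partner`
#'   (immune gene with maximal r), `r`, `p`, `passed`. Zero-variance genes
#'   never pass (no valid partner).
#' @export
coexpression_screen <- function(lnc_expr, immune_expr, r_min = 0.4,
                                p_max = 0.001) {
  if (!identical(colnames(lnc_expr), colnames(immune_expr)))
    stop_validation("lncRNA and immune matrices must share the same samples in the same order")
  n <- ncol(lnc_expr)
  if (n < 3) stop_validation("fewer than 3 shared samples")
  L <- t(log2p1(unclass(lnc_expr)))
  M <- t(log2p1(unclass(immune_expr)))
  sd_l <- apply(L, 2L, stats::sd)
  sd_m <- apply(M, 2L, stats::sd)
  ok_l <- sd_l > 0
  R <- matrix(NA_real_, nrow = ncol(L), ncol = ncol(M),
              dimnames = list(colnames(L), colnames(M)))
  if (any(ok_l) && any(sd_m > 0))
    R[ok_l, sd_m > 0] <- stats::cor(L[, ok_l, drop = FALSE],
                                    M[, sd_m > 0, drop = FALSE])
  res <- lapply(seq_len(nrow(R)), function(i) {
    r <- R[i, ]
    if (all(is.na(r)))
      return(data.frame(gene = rownames(R)[i], best_partner = NA_character_,
                        r = NA_real_, p = NA_real_, passed = FALSE))
    p <- cor_pvalue(r, n)
    pass <- any(r > r_min & p < p_max, na.rm = TRUE)
    best <- which.max(r)
    data.frame(gene = rownames(R)[i], best_partner = colnames(R)[best],
               r = r[[best]], p = p[[best]], passed = pass)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tumor-vs-normal differential expression of lncRNAs
#'
#' Two-group comparison on log2(FPKM+1): the log2 fold change is the
#' difference of group means, the p-value a Wilcoxon rank-sum test
#' (normal approximation with tie and continuity correction), and the FDR
#' Benjamini-Hochberg over all tested genes. A gene passes when
#' `|log2fc| > lfc_min` and `fdr < fdr_max`.
#'
#' @param expr `expr_matrix` with both tumor and normal samples (at least
#'   2 per group).
#' @param lfc_min minimum absolute log2 fold change, default 1.
#' @param fdr_max maximum BH-adjusted p, default 0.05.
#' @return data frame: `gene`, `log2fc` (tumor minus normal), `p_raw`,
#'   `fdr`, `direction` (`up`/`down`), `passed`.
#' @export
differential_expression <- function(expr, lfc_min = 1, fdr_max = 0.05) {
  g <- expr_group(expr)
  tum <- which(g == "tumor"); nor <- which(g == "normal")
  if (length(tum) < 2 || length(nor) < 2)
    stop_validation("each group needs at least 2 samples (tumor %d, normal %d)",
                    length(tum), length(nor))
  lx <- log2p1(unclass(expr))
  log2fc <- rowMeans(lx[, tum, drop = FALSE]) - rowMeans(lx[, nor, drop = FALSE])
  p_raw <- vapply(seq_len(nrow(lx)), function(i) {
    a <- lx[i, tum]; b <- lx[i, nor]
    if (stats::sd(c(a, b)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  fdr <- bh_adjust(p_raw)
  out <- data.frame(gene = rownames(lx), log2fc = log2fc, p_raw = p_raw,
                    fdr = fdr,
                    direction = ifelse(log2fc > 0, "up", "down"),
                    passed = abs(log2fc) > lfc_min & fdr < fdr_max)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_validation("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
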