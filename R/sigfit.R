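# Signature selection: univariate Cox screen over pairs, repeated
# cross-validated LASSO-Cox, stepwise AIC refinement, and risk scoring.
#
# The L1 penalized path is delegated to glmnet; the cross-validation repeat
# protocol, deviance computation, lambda selection and all surrounding
# statistics live here, as does the unpenalized Cox engine (coxfit.R).

align_pm_clinical <- function(pm, clinical) {
  shared <- intersect(colnames(pm$C), clinical$sample)
  if (length(shared) < 3)
    stop_validation("fewer than 3 samples shared between pair matrix and clinical table")
  cl <- clinical[match(shared, clinical$sample), , drop = FALSE]
  list(pm = subset_pair_samples(pm, shared), clinical = cl)
}

#' Univariate Cox screen over pair indicators
#'
#' Fits one single-covariate Cox model per pair and retains pairs with a
#' Wald p-value below `p_max`. Non-converged fits (e.g. separation) are
#' excluded with a warning.
#'
#' @param pm `pair_matrix` (typically prevalence-filtered).
#' @param clinical clinical table with `sample`, `futime`, `fustat`; samples
#'   are aligned by intersection with the pair matrix.
#' @param p_max Wald p-value threshold, default 0.05.
#' @return data frame, one row per retained pair: `pair`, `beta`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`. Attribute `n_tested` records the
#'   number of pairs tested. Errors if no pair is retained.
#' @export
univariate_screen <- function(pm, clinical, p_max = 0.05) {
  al <- align_pm_clinical(pm, clinical)
  pm <- al$pm; cl <- al$clinical
  rows <- vector("list", nrow(pm$C))
  n_fail <- 0L
  for (i in seq_len(nrow(pm$C))) {
    ci <- pm$C[i, ]
    if (stats::sd(ci) == 0) next
    fit <- tryCatch(
      suppressWarnings(fit_cox(cl$futime, cl$fustat,
                               matrix(ci, ncol = 1,
                                      dimnames = list(NULL, pm$pairs$pair[i])))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_fail <- n_fail + 1L; next }
    rows[[i]] <- data.frame(pair = pm$pairs$pair[i], beta = unname(fit$coef),
                            se = unname(fit$se), hr = unname(fit$hr),
                            ci_lower = unname(fit$ci_lower),
                            ci_upper = unname(fit$ci_upper),
                            p = unname(fit$p))
  }
  if (n_fail > 0)
    warning(sprintf("%d pair(s) excluded for non-convergence", n_fail),
            call. = FALSE)
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    stop_validation("univariate screen tested no usable pairs")
  out <- tab[tab$p < p_max, , drop = FALSE]
  if (!nrow(out))
    stop_validation("no pair passed the univariate screen at p < %g; cannot build a signature", p_max)
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(tab)
  out
}

#' LASSO-Cox selection with repeated cross-validation
#'
#' Fits an L1-penalized Cox model over a log-spaced lambda path and selects
#' the lambda minimizing the mean cross-validated partial-likelihood
#' deviance over `n_repeats` reshuffled fold assignments. The returned
#' subset consists of the covariates with nonzero coefficients at that
#' lambda in the full-data fit.
#'
#' @param pm `pair_matrix` restricted to univariate-retained pairs.
#' @param clinical clinical table (aligned by sample intersection).
#' @param n_folds folds per repeat, default 10 (reduced with a warning if
#'   events are fewer).
#' @param n_repeats repeats of the fold reshuffle, default 1000.
#' @param lambda_path optional decreasing lambda sequence; defaults to the
#'   full-data glmnet path.
#' @param seed integer seed driving fold assignment.
#' @return list: `selected` (pair IDs with nonzero beta), `lambda_min`,
#'   `cv` (data frame lambda / mean deviance / sd over repeats), and
#'   `coef` (nonzero penalized coefficients, for reference only — the final
#'   weights come from the unpenalized refit).
#' @export
lasso_cox_select <- function(pm, clinical, n_folds = 10L, n_repeats = 1000L,
                             lambda_path = NULL, seed = 1L) {
  al <- align_pm_clinical(pm, clinical)
  pm <- al$pm; cl <- al$clinical
  X <- t(pm$C)
  y <- cbind(time = cl$futime, status = cl$fustat)
  n_events <- sum(cl$fustat)
  if (ncol(X) < 1) stop_validation("no pairs supplied to LASSO selection")
  if (ncol(X) == 1L) {
    return(list(selected = pm$pairs$pair, lambda_min = 0,
                cv = NULL, coef = NULL))
  }
  if (n_events < n_folds) {
    warning(sprintf("only %d events; reducing folds from %d to %d",
                    n_events, n_folds, max(2L, n_events)), call. = FALSE)
    n_folds <- max(2L, n_events)
  }
  full <- glmnet::glmnet(X, y, family = "cox", lambda = lambda_path)
  lambda <- full$lambda
  dev <- with_local_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      folds <- sample(rep(seq_len(n_folds), length.out = nrow(X)))
      dsum <- numeric(length(lambda))
      for (k in seq_len(n_folds)) {
        tr <- folds != k
        fit_k <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr, , drop = FALSE],
                                family = "cox", lambda = lambda)
        bmat <- as.matrix(fit_k$beta)
        # V&VH cross-validated deviance: -2 * (pl(all) - pl(train)) at
        # the train-fold coefficients, summed over folds
        for (l in seq_along(lambda)) {
          bl <- bmat[, min(l, ncol(bmat))]
          pl_all <- cox_partial_loglik(cl$futime, cl$fustat, X, bl)
          pl_tr <- cox_partial_loglik(cl$futime[tr], cl$fustat[tr],
                                      X[tr, , drop = FALSE], bl)
          dsum[l] <- dsum[l] - 2 * (pl_all - pl_tr)
        }
      }
      dsum
    }, numeric(length(lambda)))
  })
  mean_dev <- rowMeans(dev)
  best <- which.min(mean_dev)
  lambda_min <- lambda[best]
  bsel <- as.matrix(full$beta)[, best]
  selected <- names(bsel)[bsel != 0]
  if (!length(selected)) {
    nz <- colSums(as.matrix(full$beta) != 0)
    cand <- which(nz >= 1L)
    if (!length(cand))
      stop_validation("LASSO selected no pair at any lambda")
    warning("empty selection at lambda_min; falling back to the largest lambda selecting >= 1 pair",
            call. = FALSE)
    best <- cand[1L]
    lambda_min <- lambda[best]
    bsel <- as.matrix(full$beta)[, best]
    selected <- names(bsel)[bsel != 0]
  }
  list(selected = selected, lambda_min = lambda_min,
       cv = data.frame(lambda = lambda, mean_deviance = mean_dev,
                       sd_deviance = apply(dev, 1L, stats::sd)),
       coef = bsel[bsel != 0])
}

#' Stepwise AIC refinement of a multivariate Cox model
#'
#' Backward elimination from the full covariate set: repeatedly drops the
#' single covariate whose removal most decreases the AIC, stopping when no
#' removal decreases it. For small sets (`k <= exhaustive_k`) an exhaustive
#' best-subset-by-AIC search over all non-empty subsets is used instead,
#' which the backward path can only approximate.
#'
#' @param pm `pair_matrix` restricted to the LASSO-selected pairs.
#' @param clinical clinical table.
#' @param exhaustive_k maximum set size for exhaustive subset search,
#'   default 12.
#' @return `cox_model` for the AIC-optimal subset, with element `pairs`
#'   (retained pair IDs).
#' @export
stepwise_aic <- function(pm, clinical, exhaustive_k = 12L) {
  al <- align_pm_clinical(pm, clinical)
  pm <- al$pm; cl <- al$clinical
  X <- t(pm$C)
  fit_subset <- function(cols) {
    tryCatch(
      suppressWarnings(fit_cox(cl$futime, cl$fustat, X[, cols, drop = FALSE])),
      error = function(e) NULL)
  }
  k <- ncol(X)
  if (k <= exhaustive_k) {
    best_fit <- NULL; best_cols <- NULL
    for (size in seq_len(k)) {
      for (cols in utils::combn(colnames(X), size, simplify = FALSE)) {
        f <- fit_subset(cols)
        if (is.null(f) || !f$converged) next
        if (is.null(best_fit) || f$aic < best_fit$aic) {
          best_fit <- f; best_cols <- cols
        }
      }
    }
    if (is.null(best_fit)) stop_validation("no subset produced a converged Cox fit")
    best_fit$pairs <- best_cols
    return(best_fit)
  }
  cur_cols <- colnames(X)
  cur <- fit_subset(cur_cols)
  if (is.null(cur)) stop_validation("full multivariate Cox fit failed")
  repeat {
    if (length(cur_cols) == 1L) break
    cand_aic <- rep(Inf, length(cur_cols))
    cand_fit <- vector("list", length(cur_cols))
    for (i in seq_along(cur_cols)) {
      f <- fit_subset(setdiff(cur_cols, cur_cols[i]))
      if (is.null(f) || !f$converged) next
      cand_aic[i] <- f$aic
      cand_fit[[i]] <- f
    }
    i_best <- which.min(cand_aic)
    if (cand_aic[i_best] < cur$aic) {
      cur_cols <- setdiff(cur_cols, cur_cols[i_best])
      cur <- cand_fit[[i_best]]
    } else break
  }
  cur$pairs <- cur_cols
  cur
}

#' Assemble a pair signature
#'
#' @param model final multivariate `cox_model` from [stepwise_aic()].
#' @param cutoff optional risk-score cut-off (set later by
#'   [choose_cutoff()]).
#' @return object of class `pair_signature`: `pairs`, `weights` (the
#'   multivariate Cox coefficients), `cutoff`, `model`.
#' @export
make_signature <- function(model, cutoff = NA_real_) {
  structure(list(pairs = names(model$coef),
                 weights = unname(model$coef),
                 cutoff = cutoff, model = model),
            class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("pair signature: %d pairs, cutoff = %s\n", length(x$pairs),
              format(x$cutoff, digits = 4)))
  print(data.frame(pair = x$pairs, weight = x$weights))
  invisible(x)
}

#' Risk scores from a pair signature
#'
#' RiskScore(s) = sum_i C_i(s) * W_i over the signature pairs, with C the
#' binary pair indicator and W the multivariate Cox coefficient.
#'
#' @param signature `pair_signature`.
#' @param pm `pair_matrix` containing every signature pair.
#' @return named numeric vector of per-sample risk scores.
#' @export
risk_scores <- function(signature, pm) {
  miss <- setdiff(signature$pairs, pm$pairs$pair)
  if (length(miss))
    stop_validation("signature pair(s) missing from pair matrix: %s",
                    paste(miss, collapse = ", "))
  idx <- match(signature$pairs, pm$pairs$pair)
  drop(crossprod(pm$C[idx, , drop = FALSE], signature$weights))[colnames(pm$C)]
}
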