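# Time-dependent ROC at a fixed horizon with cumulative cases (event by t)
# and dynamic controls (still at risk past t), censoring handled by the
# Kaplan-Meier estimator: with marker X, overall KM survival S(t) and
# conditional KM curves within the marker strata,
#   sensitivity(c) = [1 - S(t | X > c)] P(X > c) / [1 - S(t)]
#   specificity(c) =      S(t | X <= c) P(X <= c) /      S(t)
# Raw stratum-conditional values can be locally non-monotone; the curve is
# clamped to [0, 1] and monotonized by cumulative maxima before the
# trapezoidal AUC.

# KM survival probability at horizon t (1 if no event time <= t)
km_surv_at <- function(time, status, t) {
  if (!length(time)) return(NA_real_)
  ev_t <- sort(unique(time[status == 1 & time <= t]))
  if (!length(ev_t)) return(1)
  s <- 1
  for (tt in ev_t) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & status == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

#' Time-dependent ROC curve at a horizon
#'
#' @param risk named numeric marker vector (risk scores).
#' @param time,status survival outcome aligned with `risk` (vectors in the
#'   same order, or named like `risk`).
#' @param t horizon in days (> 0); at least one event must occur by `t`.
#' @return object of class `td_roc`: data frame `curve` with `threshold`
#'   (midpoints between sorted unique marker values plus infinite
#'   sentinels), `sensitivity`, `specificity`; scalar `auc`; `t`.
#' @export
td_roc <- function(risk, time, status, t) {
  if (t <= 0) stop_validation("horizon t must be positive")
  if (length(time) != length(risk) || length(status) != length(risk))
    stop_validation("risk, time and status must have equal length")
  if (!any(status == 1 & time <= t))
    stop_validation("no event occurs before the horizon t = %g", t)
  st <- km_surv_at(time, status, t)
  if (st >= 1 || st <= 0)
    stop_validation("degenerate overall survival S(t) = %g at t = %g", st, t)
  u <- sort(unique(risk))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    hi <- risk > thr[i]
    p_hi <- mean(hi)
    s_hi <- if (any(hi)) km_surv_at(time[hi], status[hi], t) else 1
    s_lo <- if (any(!hi)) km_surv_at(time[!hi], status[!hi], t) else 1
    sens[i] <- (1 - s_hi) * p_hi / (1 - st)
    spec[i] <- s_lo * (1 - p_hi) / st
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  # enforce monotonicity in the threshold
  sens <- rev(cummax(rev(sens)))
  spec <- cummax(spec)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc, t = t), class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at t = %g days: AUC = %.4f (%d thresholds)\n",
              x$t, x$auc, nrow(x$curve)))
  invisible(x)
}

#' Choose the risk cut-off from a time-dependent ROC curve
#'
#' Returns the threshold maximizing sensitivity + specificity (Youden-type
#' objective); ties are broken toward the smaller cut-off, which yields the
#' larger high-risk group. Infinite sentinel thresholds are not eligible.
#'
#' @param curve `td_roc` object.
#' @return list: `cutoff`, `objective` (sensitivity + specificity at the
#'   cut-off), `t` (horizon of the curve).
#' @export
choose_cutoff <- function(curve) {
  cc <- curve$curve
  cc <- cc[is.finite(cc$threshold), , drop = FALSE]
  if (nrow(cc) < 1) stop_validation("no finite threshold to choose from")
  obj <- cc$sensitivity + cc$specificity
  if (diff(range(obj)) == 0)
    warning("all cut-off objectives equal; returning the first threshold",
            call. = FALSE)
  best <- which(obj == max(obj))
  if (length(best) > 1)
    message(sprintf("cut-off objective tied at %d thresholds; choosing the smallest",
                    length(best)))
  i <- best[1L]
  list(cutoff = cc$threshold[i], objective = obj[i], t = curve$t)
}

#' Compare the risk score's ROC against clinical covariates
#'
#' Applies [td_roc()] at the same horizon to the risk score and to each
#' ordinally coded clinical covariate, returning the AUCs sorted
#' decreasingly. Single-level covariates are skipped with a warning.
#'
#' @param risk named risk-score vector.
#' @param clinical clinical table aligned with `risk` (matched on `sample`).
#' @param t horizon in days, default 1825 (5 years).
#' @return data frame `marker`, `auc`, sorted by decreasing AUC.
#' @export
compare_clinical_roc <- function(risk, clinical, t = 1825) {
  cl <- clinical[match(names(risk), clinical$sample), , drop = FALSE]
  ord <- encode_clinical_ordinal(cl)
  markers <- c(list(risk_score = unname(risk)),
               as.list(ord))
  out <- lapply(names(markers), function(nm) {
    v <- markers[[nm]]
    ok <- !is.na(v)
    if (length(unique(v[ok])) < 2) {
      warning(sprintf("marker '%s' has a single level; skipped", nm),
              call. = FALSE)
      return(NULL)
    }
    roc <- td_roc(v[ok], cl$futime[ok], cl$fustat[ok], t)
    data.frame(marker = nm, auc = roc$auc)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign high/low risk groups at a cut-off
#'
#' A sample is high-risk when its score is strictly greater than the
#' cut-off.
#'
#' @param risk named risk-score vector.
#' @param cutoff finite cut-off.
#' @return named factor with levels `high`, `low`. Errors if either group
#'   is empty (downstream two-group tests would be undefined).
#' @export
assign_groups <- function(risk, cutoff) {
  if (!is.finite(cutoff)) stop_validation("cutoff must be finite")
  g <- factor(ifelse(risk > cutoff, "high", "low"), levels = c("high", "low"))
  names(g) <- names(risk)
  if (any(table(g) == 0))
    stop_validation("cut-off %g leaves an empty risk group", cutoff)
  g
}
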