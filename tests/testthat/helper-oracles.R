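# Independent oracles used by the tests. These are deliberately naive
# implementations (explicit sums, full enumeration, grid search) kept
# separate from the package's own code paths.

# Explicitly summed Breslow/Efron partial log-likelihood for one covariate,
# tie-free data: for each event i, eta_i - log(sum_{t_j >= t_i} e^eta_j).
naive_partial_loglik <- function(time, status, x, beta) {
  eta <- x * beta
  ll <- 0
  for (i in which(status == 1)) {
    rs <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[rs])))
  }
  ll
}

# Brute-force grid maximization of the naive partial likelihood with two
# refinement passes around the incumbent.
grid_max_beta <- function(time, status, x, lo = -6, hi = 6) {
  g <- seq(lo, hi, by = 0.01)
  ll <- vapply(g, function(b) naive_partial_loglik(time, status, x, b), 0)
  b0 <- g[which.max(ll)]
  for (step in c(1e-3, 1e-4, 1e-5)) {
    g <- seq(b0 - 25 * step, b0 + 25 * step, by = step)
    ll <- vapply(g, function(b) naive_partial_loglik(time, status, x, b), 0)
    b0 <- g[which.max(ll)]
  }
  b0
}

# Mann-Whitney AUC of marker x for cases vs controls (ties credit 0.5).
mw_auc <- function(x_case, x_ctrl) {
  cmp <- outer(x_case, x_ctrl, ">") + 0.5 * outer(x_case, x_ctrl, "==")
  mean(cmp)
}

# Benjamini-Hochberg step-up by direct definition.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided rank-sum p by full enumeration of group assignments:
# P(|U - E[U]| >= |U_obs - E[U]|) under the permutation null.
exact_ranksum_p <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2)
  vals <- c(v1, v2)
  r <- rank(vals)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  dev_obs <- abs(u_obs - mu)
  sets <- utils::combn(n1 + n2, n1, simplify = FALSE)
  mean(vapply(sets, function(s) abs(u_of(s) - mu) >= dev_obs - 1e-12, TRUE))
}

# Pearson chi-square statistic by the definition sum (O-E)^2 / E.
naive_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Log-rank statistic via the package is tested against a label-permutation
# null; this helper just reshuffles labels.
permute_logrank_stats <- function(time, status, group, n_perm, seed) {
  set.seed(seed)
  replicate(n_perm, {
    g <- sample(group)
    logrank_test(time, status, g)$statistic
  })
}

# KM median survival time: first event time with S <= 0.5 (Inf if never).
km_median <- function(time, status) {
  km <- km_estimate(time, status)
  i <- which(km$surv <= 0.5)
  if (!length(i)) Inf else km$time[i[1]]
}

# small deterministic survival fixture without ties
tiny_surv <- function(n, seed, p_cens = 0.3, beta = 0) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  while (length(unique(x)) < 2) x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.1 * exp(beta * x))
  cens <- rbinom(n, 1, p_cens)
  list(time = tt, status = 1 - cens, x = x)
}

# compact synthetic configuration for module-level tests
small_sim_config <- function(seed, ...) {
  sim_config(n_tumor = 150L, n_normal = 30L, n_lnc = 60L, n_imm = 30L,
             n_coexpr = 20L, n_de = 14L, n_true_pairs = 2L, seed = seed, ...)
}
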