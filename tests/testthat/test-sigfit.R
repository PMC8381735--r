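test_that("Newton Cox solution matches grid maximization of the summed partial likelihood", {
  set.seed(11)
  n_checked <- 0
  for (i in 1:20) {
    repeat {
      d <- tiny_surv(n = sample(5:8, 1), seed = 1000 + i * 7 + n_checked)
      if (sum(d$status) >= 2 && length(unique(d$x[d$status == 1])) == 2 &&
          anyDuplicated(d$time) == 0) break
      n_checked <- n_checked + 1
    }
    b_grid <- grid_max_beta(d$time, d$status, d$x)
    if (abs(b_grid) > 5.5) next   # near-separated draw; MLE not interior
    fit <- fit_cox(d$time, d$status, d$x)
    expect_lt(abs(unname(fit$coef) - b_grid), 1e-4)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})

test_that("Cox engine agrees with an established implementation, with and without ties", {
  skip_if_not_installed("survival")
  set.seed(12)
  for (i in 1:5) {
    n <- 120
    x <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n))
    tt <- ceiling(rexp(n, 0.05 * exp(0.6 * x[, "a"] - 0.4 * x[, "b"])))
    cc <- ceiling(rexp(n, 0.03))
    time <- pmin(tt, cc); status <- as.integer(tt <= cc)
    fit <- fit_cox(time, status, x)
    ref <- survival::coxph(survival::Surv(time, status) ~ x, ties = "efron")
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-9)
  }
})

test_that("Cox MLE is consistent for the true log-hazard ratio", {
  betas <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    x <- rbinom(1000, 1, 0.5)
    tt <- rexp(1000, 0.01 * exp(1.0 * x))
    unname(fit_cox(tt, rep(1, 1000), x)$coef)
  }, 0)
  expect_lt(abs(median(betas) - 1.0), 0.15)
})

test_that("Cox bookkeeping: AIC identity, CI ordering, null p-values, separation flag", {
  d <- tiny_surv(200, seed = 5)
  fit <- fit_cox(d$time, d$status, cbind(z = d$x, w = rnorm(200)))
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_true(all(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper))
  expect_error(fit_cox(d$time, d$status, rep(1, 200)), "constant")
  expect_error(fit_cox(d$time, rep(0, 200), d$x), "at least one event")

  # null covariate: Wald p approximately uniform across seeds
  ps <- vapply(1:50, function(s) {
    set.seed(300 + s)
    x <- rnorm(200)
    tt <- rexp(200, 0.05)
    unname(fit_cox(tt, rep(1, 200), x)$p)
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # perfectly separating covariate is flagged
  time <- c(1:5, 10:14) + 0.5
  xsep <- rep(c(1, 0), each = 5)
  expect_warning(fsep <- fit_cox(time, rep(1, 10), xsep), "separation")
  expect_false(fsep$converged)
})

test_that("flipping a pair's indicator flips its beta and preserves the log-likelihood", {
  d <- tiny_surv(150, seed = 8, beta = 0.9)
  f1 <- fit_cox(d$time, d$status, d$x)
  f2 <- fit_cox(d$time, d$status, 1 - d$x)
  expect_equal(unname(f1$coef), -unname(f2$coef), tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

make_pm <- function(C, samples = paste0("s", seq_len(ncol(C)))) {
  colnames(C) <- samples
  rownames(C) <- rownames(C) %||% paste0("p", seq_len(nrow(C)))
  pairs <- data.frame(geneA = rownames(C), geneB = rownames(C),
                      pair = rownames(C))
  lncPairSig:::new_pair_matrix(pairs, C)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("univariate screen retains planted pairs and halts when nothing passes", {
  set.seed(21)
  n <- 300
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    Ck <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 5e-4 * exp(1.0 * Ck))
    cl <- data.frame(sample = paste0("s", 1:n), futime = tt,
                     fustat = rep(1, n))
    pm <- make_pm(rbind(true_pair = Ck, noise = rbinom(n, 1, 0.5)))
    uni <- univariate_screen(pm, cl, p_max = 0.05)
    if ("true_pair" %in% uni$pair && uni$hr[uni$pair == "true_pair"] > 1)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  set.seed(23)
  pm0 <- make_pm(rbind(a = rbinom(50, 1, 0.5)))
  cl0 <- data.frame(sample = paste0("s", 1:50), futime = rexp(50, 0.01),
                    fustat = rep(1, 50))
  expect_error(univariate_screen(pm0, cl0, p_max = 1e-12), "no pair passed")
})

test_that("LASSO selection recovers strong pairs and respects the penalty limit", {
  set.seed(31)
  n <- 400
  strong <- replicate(3, rbinom(n, 1, runif(1, 0.3, 0.7)))
  noise <- replicate(30, rbinom(n, 1, runif(1, 0.3, 0.7)))
  eta <- drop(strong %*% c(1, 1, -1))
  tt <- rexp(n, 5e-4 * exp(eta))
  C <- t(cbind(strong, noise))
  rownames(C) <- c(paste0("strong", 1:3), paste0("noise", 1:30))
  pm <- make_pm(C)
  cl <- data.frame(sample = colnames(pm$C), futime = tt, fustat = rep(1, n))
  sel <- lasso_cox_select(pm, cl, n_repeats = 3, seed = 5)
  expect_true(all(paste0("strong", 1:3) %in% sel$selected))

  # only absurdly large penalties in the path: nothing can be selected
  expect_error(
    suppressWarnings(lasso_cox_select(pm, cl, n_repeats = 1,
                                      lambda_path = c(50, 40), seed = 5)),
    "no pair")

  # a dominant lambda makes the choice invariant to the repeat count
  sel2 <- lasso_cox_select(pm, cl, n_repeats = 6, seed = 5)
  expect_setequal(sel$selected, sel2$selected)
})

test_that("stepwise AIC drops noise, keeps strong effects, and equals exhaustive search for small sets", {
  # AIC removes an uninformative covariate with probability
  # P(chisq_1 < 2) ~ 0.84; over 20 seeds, 13+ drops is ~3 SD below the mean
  dropped <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    n <- 400
    c1 <- rbinom(n, 1, 0.5); c2 <- rbinom(n, 1, 0.4); cn <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 5e-4 * exp(1.2 * c1 - 1.2 * c2))
    pm <- make_pm(rbind(s1 = c1, s2 = c2, noise = cn))
    cl <- data.frame(sample = colnames(pm$C), futime = tt, fustat = rep(1, n))
    fit <- stepwise_aic(pm, cl)
    if (!("noise" %in% fit$pairs)) dropped <- dropped + 1L
    expect_true(all(c("s1", "s2") %in% fit$pairs))
    # backward elimination agrees with the exhaustive best subset here
    fit_bw <- stepwise_aic(pm, cl, exhaustive_k = 0L)
    expect_lte(fit$aic, fit_bw$aic + 1e-9)
  }
  expect_gte(dropped, 13L)
})

test_that("risk scores are exact dot products with zero-weight invariance", {
  C <- rbind(p1 = c(1L, 0L, 1L), p2 = c(1L, 1L, 0L), p3 = c(0L, 0L, 0L))
  pm <- make_pm(C)
  model <- structure(list(coef = c(p1 = 0.5, p2 = -0.2)), class = "cox_model")
  sig <- make_signature(model)
  r <- risk_scores(sig, pm)
  expect_equal(unname(r), c(0.3, -0.2, 0.5))
  model2 <- structure(list(coef = c(p1 = 0.5, p2 = -0.2, p3 = 0)),
                      class = "cox_model")
  expect_equal(unname(risk_scores(make_signature(model2), pm)), unname(r))
  sig_missing <- make_signature(structure(list(coef = c(px = 1)),
                                          class = "cox_model"))
  expect_error(risk_scores(sig_missing, pm), "missing from pair matrix")
})
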