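test_that("Kaplan-Meier product-limit identities", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  # all censored: empty event table, survival constant at 1
  expect_equal(nrow(km_estimate(c(1, 2, 3), c(0, 0, 0))), 0L)

  # no censoring: equals the empirical survival function at event times
  set.seed(51)
  for (i in 1:10) {
    tt <- sample(1:50, 20, replace = TRUE) + runif(20)
    km <- km_estimate(tt, rep(1, 20))
    expect_equal(km$surv, vapply(km$time, function(u) mean(tt > u), 0),
                 tolerance = 1e-12)
  }
  expect_error(km_estimate(numeric(), numeric()), "empty")
})

test_that("log-rank test: null identity, permutation consistency, and reference agreement", {
  # two identical groups interleaved: statistic 0
  tt <- rep(c(3, 7, 11, 20), 2) + 0.5
  st <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(tt, st, g)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)

  set.seed(52)
  n <- 60
  grp <- rep(c("hi", "lo"), each = n / 2)
  time <- rexp(n, 0.05 * exp(0.8 * (grp == "hi")))
  status <- rbinom(n, 1, 0.8)
  lr <- logrank_test(time, status, grp)
  perm <- permute_logrank_stats(time, status, grp, n_perm = 400, seed = 7)
  p_perm <- mean(perm >= lr$statistic - 1e-12)
  mc_err <- 3 * sqrt(max(p_perm, lr$p) / 400) + 0.01
  expect_lt(abs(p_perm - lr$p), max(0.05, mc_err))

  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
})

test_that("chi-square association matches the Pearson definition", {
  g <- rep(c("high", "low"), each = 20)
  cat_indep <- rep(rep(c("A", "B"), each = 10), 2)
  r <- suppressWarnings(chisq_association(g, cat_indep))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  cat_perf <- rep(c("A", "B"), each = 20)
  r2 <- chisq_association(g, cat_perf)
  expect_equal(r2$statistic, 40)
  expect_equal(r2$df, 1L)

  set.seed(53)
  for (i in 1:10) {
    g <- sample(c("x", "y"), 60, replace = TRUE)
    cc <- sample(c("A", "B", "C"), 60, replace = TRUE)
    tab <- table(g, cc)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    r <- suppressWarnings(chisq_association(g, cc))
    expect_equal(r$statistic, naive_chisq(tab), tolerance = 1e-10)
  }
  expect_error(chisq_association(rep("high", 10), rep(c("A", "B"), 5)),
               "degenerate")
})

test_that("rank-sum test agrees with exact enumeration on small groups", {
  v <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  r <- ranksum_compare(v, g)
  expect_equal(unname(r$statistic), 0)     # U = 0: complete separation
  expect_identical(r$direction, "a < b")
  expect_equal(exact_ranksum_p(v[1:3], v[4:6]), 0.1)  # 2/20 enumerated

  set.seed(54)
  for (i in 1:12) {
    n1 <- sample(5:8, 1); n2 <- sample(5:8, 1)
    v1 <- rnorm(n1); v2 <- rnorm(n2, mean = runif(1, 0, 1.5))
    r <- ranksum_compare(c(v1, v2), rep(c("g1", "g2"), c(n1, n2)))
    expect_lt(abs(r$p - exact_ranksum_p(v1, v2)), 0.02)
  }

  same <- rep(1:4, 2)
  r0 <- ranksum_compare(same, rep(c("a", "b"), each = 4))
  expect_identical(r0$direction, "equal medians")
  expect_gt(r0$p, 0.9)
  expect_error(ranksum_compare(1:3, factor(rep("a", 3), levels = c("a", "b"))),
               "non-empty")

  multi <- ranksum_compare(rnorm(30), rep(c("I", "II", "III"), 10),
                           mode = "pairwise")
  expect_equal(nrow(multi), 3L)
  rest <- ranksum_compare(rnorm(30), rep(c("I", "II", "III"), 10),
                          mode = "level_vs_rest")
  expect_equal(nrow(rest), 3L)
})

test_that("independence Cox: k = 1 identity and planted risk-score signal", {
  co <- simulate_cohort(sim_config(n_tumor = 250L, n_normal = 30L,
                                   n_lnc = 60L, n_imm = 30L, n_coexpr = 20L,
                                   n_de = 14L, n_true_pairs = 2L, seed = 61))
  cl <- filter_clinical(co$clinical)
  eta <- co$truth$true_linear_predictor[cl$sample]
  res <- independence_cox(cl, eta)
  rs_uni <- res$univariate[res$univariate$covariate == "risk_score", ]
  rs_mv <- res$multivariate[res$multivariate$covariate == "risk_score", ]
  expect_gt(rs_uni$hr, 1)
  expect_lt(rs_mv$p, 0.05)

  # single covariate: univariate and multivariate fits coincide exactly
  cl1 <- cl[, c("sample", "futime", "fustat")]
  res1 <- independence_cox(cl1, eta)
  expect_identical(res1$univariate$covariate, "risk_score")
  expect_equal(res1$univariate$hr, res1$multivariate$hr, tolerance = 1e-10)
  expect_equal(res1$univariate$p, res1$multivariate$p, tolerance = 1e-10)
})

test_that("immune correlation recovers planted directions and handles degenerate columns", {
  risk <- setNames(seq(-2, 2, length.out = 50), paste0("s", 1:50))
  fr <- data.frame(sample = names(risk),
                   same = unname(risk),
                   flat = rep(0.2, 50),
                   anti = unname(-risk) + rnorm(50, 0, 1e-6))
  expect_warning(tab <- immune_correlation(risk, fr), "constant")
  expect_equal(tab$rho[tab$cell_type == "same"], 1)
  expect_equal(tab$p[tab$cell_type == "same"], 0)
  expect_lt(tab$rho[tab$cell_type == "anti"], -0.999)
  expect_false("flat" %in% tab$cell_type)

  hits <- 0L
  for (s in 1:5) {
    co <- simulate_cohort(small_sim_config(seed = 700 + s))
    eta <- co$truth$true_linear_predictor
    tab <- immune_correlation(eta, co$immune_fractions)
    pos <- names(co$truth$cell_effects)[co$truth$cell_effects > 0]
    sub <- tab[tab$cell_type %in% pos, ]
    if (all(sub$rho > 0 & sub$p < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("drug-sensitivity comparison finds planted IC50 shifts and flags the control drug", {
  hits <- 0L; ctrl_sig <- 0L
  for (s in 1:5) {
    co <- simulate_cohort(small_sim_config(seed = 800 + s))
    eta <- co$truth$true_linear_predictor
    grp <- factor(ifelse(eta > median(eta), "high", "low"),
                  levels = c("high", "low"))
    names(grp) <- names(eta)
    tab <- drug_sensitivity_compare(grp, co$ic50)
    planted <- names(co$truth$drug_effects)[co$truth$drug_effects > 0]
    sub <- tab[tab$drug %in% planted, ]
    if (all(sub$p < 0.05 & sub$median_high < sub$median_low)) hits <- hits + 1L
    if (tab$p[tab$drug == "Gemcitabine"] < 0.05) ctrl_sig <- ctrl_sig + 1L
  }
  expect_gte(hits, 4L)
  expect_lte(ctrl_sig, 2L)

  g1 <- factor(c(a = "high", b = "low"), levels = c("high", "low"))
  expect_error(drug_sensitivity_compare(g1, data.frame(sample = c("a", "b"),
                                                       d = c(1, 2))),
               "at least 2")
})
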