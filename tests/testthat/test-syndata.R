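test_that("invalid configurations are rejected", {
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_de = 300, n_lnc = 200), "n_de")
  expect_error(sim_config(n_true_pairs = 50, n_de = 10, n_coexpr = 10),
               "disjoint pairs")
  expect_error(sim_config(beta_range = c(2, 1)), "beta_range")
})

test_that("same config and seed reproduce the cohort exactly", {
  cfg <- small_sim_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$expr), unclass(b$expr))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$true_pairs, b$truth$true_pairs)
  expect_identical(a$ic50, b$ic50)
})

test_that("zero-effect configuration yields a null linear predictor", {
  cfg <- small_sim_config(seed = 3, beta_range = c(0, 0))
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$true_linear_predictor == 0))
  expect_true(all(co$truth$true_pairs$beta == 0))
})

test_that("eta equals the dot product of true betas with pair indicators", {
  co <- simulate_cohort(small_sim_config(seed = 5))
  tp <- co$truth$true_pairs
  tum <- colnames(co$expr)[attr(co$expr, "group") == "tumor"]
  pm <- encode_pairs(co$expr[unique(c(tp$geneA, tp$geneB)), tum])
  ids <- paste(tp$geneA, tp$geneB, sep = "|")
  eta <- drop(crossprod(pm$C[ids, , drop = FALSE], tp$beta))
  expect_equal(unname(eta), unname(co$truth$true_linear_predictor[tum]),
               tolerance = 1e-12)
  # and every true-pair gene is a lncRNA in the matrix
  expect_true(all(c(tp$geneA, tp$geneB) %in%
                    co$catalog$gene_id[co$catalog$biotype == "lncRNA"]))
})

test_that("planted co-expression exceeds r = 0.4 against anchors (median over seeds)", {
  rs <- sapply(1:10, function(s) {
    co <- simulate_cohort(sim_config(n_tumor = 270L, n_normal = 40L,
                                     n_lnc = 40L, n_imm = 20L,
                                     n_coexpr = 10L, n_de = 8L,
                                     n_true_pairs = 2L, seed = s))
    lx <- log2(unclass(co$expr) + 1)
    anch <- co$truth$params$anchors
    vapply(names(anch), function(g) cor(lx[g, ], lx[anch[g], ]), 0)
  })
  expect_true(all(apply(rs, 1L, median) > 0.4))
})

test_that("realized censoring tracks the target and survival effects point the right way", {
  co <- simulate_cohort(sim_config(seed = 9))   # 600 tumors, default regime
  expect_lt(abs(mean(1 - co$clinical$fustat) - 0.5), 0.10)
  tp <- co$truth$true_pairs
  tum <- co$clinical$sample
  for (k in seq_len(nrow(tp))) {
    if (abs(tp$beta[k]) < 0.8) next
    sub <- co$expr[c(tp$geneA[k], tp$geneB[k]), tum]
    Ck <- encode_pairs(sub)$C[1L, ]
    m1 <- km_median(co$clinical$futime[Ck == 1], co$clinical$fustat[Ck == 1])
    m0 <- km_median(co$clinical$futime[Ck == 0], co$clinical$fustat[Ck == 0])
    if (tp$beta[k] > 0) expect_lt(m1, m0) else expect_gt(m1, m0)
  }
})

test_that("write_cohort round-trips through the ingest readers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(small_sim_config(seed = 21))
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(unclass(back$expr), unclass(co$expr), tolerance = 1e-12)
  expect_identical(attr(back$expr, "group"), attr(co$expr, "group"))
  expect_equal(back$truth$true_pairs$beta, co$truth$true_pairs$beta,
               tolerance = 1e-12)
  expect_identical(back$truth$true_pairs$geneA, co$truth$true_pairs$geneA)
  expect_equal(back$clinical$futime, co$clinical$futime, tolerance = 1e-9)
  expect_error(write_cohort(co, ""), "non-empty")
})

test_that("a regenerated cohort reuses the planted structure but not the samples", {
  cfg <- small_sim_config(seed = 2)
  train <- simulate_cohort(cfg)
  cfg2 <- cfg; cfg2$seed <- 777L
  test <- simulate_cohort(cfg2, truth = train$truth)
  expect_identical(test$truth$true_pairs, train$truth$true_pairs)
  expect_identical(test$truth$de_gene_ids, train$truth$de_gene_ids)
  expect_false(isTRUE(all.equal(unclass(test$expr), unclass(train$expr))))
})
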