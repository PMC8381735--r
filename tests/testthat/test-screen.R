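make_expr <- function(vals, group) lncPairSig:::make_expr_matrix(vals, group)

test_that("co-expression screen identities and degenerate genes", {
  set.seed(1)
  n <- 40
  g <- setNames(rep(c("tumor", "normal"), c(30, 10)), paste0("s", 1:n))
  imm <- matrix(2^rnorm(2 * n, 5), 2, n,
                dimnames = list(c("IMM1", "IMM2"), names(g)))
  lnc <- rbind(LNCcopy = imm["IMM1", ],          # exact copy: r = 1
               LNCflat = rep(3, n),              # zero variance
               LNCnoise = 2^rnorm(n, 5))
  colnames(lnc) <- names(g)
  res <- coexpression_screen(make_expr(lnc, g), make_expr(imm, g))
  expect_true(res$passed[res$gene == "LNCcopy"])
  expect_equal(res$r[res$gene == "LNCcopy"], 1)
  expect_equal(res$p[res$gene == "LNCcopy"], 0)
  expect_false(res$passed[res$gene == "LNCflat"])
  expect_false(res$passed[res$gene == "LNCnoise"])

  # permuting samples consistently leaves r unchanged
  perm <- sample(n)
  res2 <- coexpression_screen(make_expr(lnc[, perm], g[perm]),
                              make_expr(imm[, perm], g[perm]))
  expect_equal(res2$r, res$r, tolerance = 1e-12)

  expect_error(coexpression_screen(make_expr(lnc[, 1:2], g[1:2]),
                                   make_expr(imm[, 1:2], g[1:2])),
               "fewer than 3")
})

test_that("differential expression: fold-change arithmetic and boundary behavior", {
  g <- setNames(rep(c("tumor", "normal"), c(4, 4)), paste0("s", 1:8))
  vals <- rbind(same = rep(7, 8),
                x4 = c(rep(63, 4), rep(15, 4)))  # log2(64) - log2(16) = 2
  colnames(vals) <- names(g)
  de <- differential_expression(make_expr(vals, g), lfc_min = 1, fdr_max = 1)
  expect_equal(de$log2fc[de$gene == "same"], 0)
  expect_false(de$passed[de$gene == "same"])
  expect_equal(de$log2fc[de$gene == "x4"], 2)
  expect_identical(de$direction[de$gene == "x4"], "up")

  expect_error(differential_expression(
    make_expr(vals[, 1:5], g[1:5])), "at least 2 samples")
})

test_that("planted DE lncRNAs are recovered with controlled FDR", {
  hits <- sapply(1:5, function(s) {
    co <- simulate_cohort(small_sim_config(seed = 100 + s))
    parts <- partition_genes(co$expr, co$catalog)
    coex <- coexpression_screen(parts$lnc, parts$immune)
    de <- differential_expression(parts$lnc[coex$gene[coex$passed], , drop = FALSE])
    called <- de$gene[de$passed]
    truth <- co$truth$de_gene_ids
    c(recall = mean(truth %in% called),
      fdr = if (length(called)) mean(!(called %in% truth)) else 0)
  })
  expect_gte(mean(hits["recall", ]), 0.8)
  expect_lte(mean(hits["fdr", ]), 0.10)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
  }
  # monotone non-decreasing on sorted input
  p <- sort(runif(25))
  expect_true(all(diff(bh_adjust(p)) >= -1e-12))
})

test_that("screen pass-sets shrink when thresholds tighten", {
  co <- simulate_cohort(small_sim_config(seed = 31))
  parts <- partition_genes(co$expr, co$catalog)
  loose <- coexpression_screen(parts$lnc, parts$immune, r_min = 0.3, p_max = 0.01)
  tight <- coexpression_screen(parts$lnc, parts$immune, r_min = 0.5, p_max = 0.001)
  expect_true(all(tight$gene[tight$passed] %in% loose$gene[loose$passed]))
  de_loose <- differential_expression(parts$lnc, lfc_min = 0.5, fdr_max = 0.1)
  de_tight <- differential_expression(parts$lnc, lfc_min = 1.5, fdr_max = 0.01)
  expect_true(all(de_tight$gene[de_tight$passed] %in%
                    de_loose$gene[de_loose$passed]))
})
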