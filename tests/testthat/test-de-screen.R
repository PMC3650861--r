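test_that("group fold-change is the ratio of linear group means", {
  # constructed input reproducing the printed cirrhosis fold-change of
  # EPCAM: normal mean 100, cirrhosis mean 1480 -> 14.8
  m <- rbind(EPCAM = c(90, 110, 100, 1400, 1560, 1480, 1480))
  e <- make_expr(m, c("NOR", "NOR", "NOR", "CIR", "CIR", "CIR", "CIR"))
  expect_equal(group_fold_change(e, "EPCAM", "CIR"), 14.8)
  expect_equal(group_fold_change(e, "EPCAM", "NOR"), 1.0)

  set.seed(81)
  m2 <- named_matrix(matrix(2^rnorm(60, 8), 5))
  e2 <- make_expr(m2, rep(c("NOR", "CIR"), each = 6))
  for (g in rownames(m2)) {
    oracle <- mean(m2[g, 7:12]) / mean(m2[g, 1:6])
    expect_equal(group_fold_change(e2, g, "CIR"), oracle, tolerance = 1e-12)
  }
})

test_that("fold-change scales exactly with one group's values", {
  set.seed(82)
  m <- named_matrix(matrix(2^rnorm(40, 8), 4))
  e <- make_expr(m, rep(c("NOR", "CIR"), each = 5))
  base <- vapply(rownames(m), function(g) group_fold_change(e, g, "CIR"), 0)
  m2 <- m; m2[, 6:10] <- m2[, 6:10] * 3.7
  e2 <- make_expr(m2, rep(c("NOR", "CIR"), each = 5))
  scaled <- vapply(rownames(m), function(g) group_fold_change(e2, g, "CIR"), 0)
  expect_equal(scaled, base * 3.7, tolerance = 1e-12)
})

test_that("the Fisher combination matches its closed form", {
  # p_t = p_f = 0.05: X = -4 ln 0.05 = 11.98...;
  # chi-square(4) survival S(x) = (1 + x/2) exp(-x/2) ~ 0.0175
  X <- -2 * (log(0.05) + log(0.05))
  expect_equal(X, 11.98293, tolerance = 1e-5)
  p_oracle <- (1 + X / 2) * exp(-X / 2)
  expect_equal(stats::pchisq(X, 4, lower.tail = FALSE), p_oracle,
               tolerance = 1e-12)
  expect_equal(p_oracle, 0.01748, tolerance = 1e-4)
})

test_that("mean-variance test components match t.test and var.test", {
  set.seed(83)
  for (i in 1:5) {
    x <- rnorm(12, 0, 1); y <- rnorm(30, 0.4, 1.6)
    r <- mean_variance_test(x, y)
    expect_equal(r$p_t, stats::t.test(x, y)$p.value, tolerance = 1e-10)
    expect_equal(r$p_f, stats::var.test(x, y)$p.value, tolerance = 1e-10)
    X <- -2 * (log(r$p_t) + log(r$p_f))
    expect_equal(r$p_combined, stats::pchisq(X, 4, lower.tail = FALSE))
  }
})

test_that("element-wise identical samples put all signal in the F term", {
  x <- c(1, 2, 3, 4, 5)
  r <- mean_variance_test(x, x)
  expect_equal(r$p_t, 1)
  expect_equal(r$p_f, 1)
  expect_equal(r$p_combined,
               stats::pchisq(-2 * (log(1) + log(1)), 4, lower.tail = FALSE))
  expect_warning(mean_variance_test(c(2, 2, 2), c(2, 2, 2)), "zero variance")
})

test_that("the combined test is calibrated when t and f are independent", {
  set.seed(84)
  u1 <- runif(1e4); u2 <- runif(1e4)
  p <- stats::pchisq(-2 * (log(u1) + log(u2)), 4, lower.tail = FALSE)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
  expect_true(all(p <= 1))
})

test_that("variance-only shifts are caught far more often than by t alone", {
  set.seed(85)
  reps <- 1000
  x <- matrix(rnorm(reps * 12, 0, 1), reps)
  y <- matrix(rnorm(reps * 49, 0, 2), reps)
  r <- livdevscreen:::row_mean_variance_test(x, y)
  rate_comb <- mean(r$p_combined < 0.001)
  rate_t <- mean(r$p_t < 0.001)
  expect_gte(rate_comb, 5 * max(rate_t, 1e-12))
  expect_gt(rate_comb, 0.05)
})

test_that("screening composes fold-change and the combined test", {
  set.seed(86)
  m <- named_matrix(matrix(2^rnorm(6 * 16, 8, 0.5), 6))
  e <- make_expr(m, rep(c("NOR", "CIR", "HCC_EARLY", "HCC_LATE"), each = 4))
  de <- screen_gene_set(e, rownames(m))
  g <- rownames(m)[3]
  lg <- log2(m[3, ])
  direct <- mean_variance_test(lg[5:8], lg[1:4])
  i <- match(g, de$gene_id)
  expect_equal(de$NOR_CIR_p_comb[i], direct$p_combined)
  expect_equal(de$NOR_CIR_fc[i], group_fold_change(e, g, "CIR"))
  expect_warning(screen_gene_set(e, c(rownames(m), "nope")), "nope")
})

test_that("the screen's type-I rate at alpha 0.001 is near nominal", {
  genes <- sprintf("N%04d", 1:4000)
  sim <- generate_cohort(cohort_config(genes, master_seed = 55))
  de <- screen_gene_set(sim$expr, genes)
  for (cn in c("NOR_CIR_sig", "NOR_EARLY_sig", "CIR_HCC_sig"))
    expect_lte(mean(de[[cn]]), 0.003)
})

test_that("pattern classification reproduces the printed archetypes", {
  row <- function(fc_cir, fc_tumor_vs_cir, sigC, sigE, sigL, sigCH) {
    data.frame(NOR_CIR_fc = fc_cir, CIR_HCC_fc = fc_tumor_vs_cir,
               NOR_CIR_sig = sigC, NOR_EARLY_sig = sigE,
               NOR_LATE_sig = sigL, CIR_HCC_sig = sigCH)
  }
  # EPCAM-like: cirrhosis 14.8, tumors 14.0/5.7 -> pooled decline, sig
  expect_equal(classify_pattern(row(14.8, 10.9 / 14.8, TRUE, TRUE, TRUE, TRUE)),
               "CIR_PEAK")
  # DKK1-like: unchanged in cirrhosis, tumors 3.8/1.8
  expect_equal(classify_pattern(row(1.05, 2.9, FALSE, TRUE, TRUE, FALSE)),
               "TUMOR_ONLY")
  # GPC3-like: x2 in cirrhosis, x7-10 in tumors -> amplified
  expect_equal(classify_pattern(row(2, 8.5 / 2, TRUE, TRUE, TRUE, TRUE)),
               "SHARED_AMPLIFIED")
  expect_equal(classify_pattern(row(0.5, 1.05, TRUE, FALSE, FALSE, FALSE)),
               "DOWN_PERSISTENT")
  expect_equal(classify_pattern(row(1, 1, FALSE, FALSE, TRUE, FALSE)),
               "LATE_ONLY")
  expect_equal(classify_pattern(row(2, 1, TRUE, TRUE, FALSE, FALSE)),
               "SHARED_SIMILAR")
  expect_equal(classify_pattern(row(1, 1, FALSE, FALSE, FALSE, FALSE)),
               "UNCHANGED")
})

test_that("every screened gene gets exactly one pattern label", {
  sim <- small_cohort(n_genes = 30, seed = 57)
  de <- screen_gene_set(sim$expr, rownames(sim$expr$exprs))
  labels <- c("CIR_PEAK", "DOWN_PERSISTENT", "TUMOR_ONLY", "LATE_ONLY",
              "SHARED_AMPLIFIED", "SHARED_SIMILAR", "UNCHANGED")
  expect_true(all(de$pattern %in% labels))
  expect_equal(length(de$pattern), 30)
})

test_that("the study-mimic cohort recovers the planted pattern classes", {
  sim <- mimic_cohort()
  reg <- mimic_registry()
  de <- screen_gene_set(sim$expr, reg$liver_dev$gene_id)
  truthpat <- reg$liver_dev$pattern[match(de$gene_id, reg$liver_dev$gene_id)]
  # EPCAM-like genes are flagged both against normal and against cirrhosis
  strong_cp <- c("EPCAM", "MMP7", "KRT19", "MMP2", "VIM", "SOX9")
  i <- match(strong_cp, de$gene_id)
  expect_true(all(de$NOR_CIR_sig[i]))
  expect_true(all(de$CIR_HCC_sig[i]))
  expect_true(all(de$pattern[i] == "CIR_PEAK"))
  # planted unchanged genes rarely drift into a called pattern
  unchanged <- truthpat == "UNCHANGED"
  expect_gte(mean(de$pattern[unchanged] == "UNCHANGED"), 0.95)
})
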