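make_probes <- function(m, gc = NULL, tm = NULL, pos = NULL) {
  n <- nrow(m)
  if (is.null(gc)) gc <- seq(0.3, 0.8, length.out = n)
  if (is.null(tm)) tm <- 50 + 40 * (gc - 0.3) / 0.5
  if (is.null(pos)) pos <- seq_len(n) - 1L
  colnames(m) <- sprintf("a%d", seq_len(ncol(m)))
  probe_table(data.frame(probe_id = sprintf("p%d", seq_len(n)),
                         gene_id = sprintf("g%d", seq_len(n)),
                         gc_fraction = gc, melting_temp = tm,
                         position_index = pos), m)
}

test_that("background correction subtracts the floor quantile and clamps", {
  p0 <- make_probes(matrix(c(10, 100, 1000), 3))
  expect_equal(background_correct(p0, floor_quantile = 0)$intensities,
               p0$intensities)
  p1 <- make_probes(matrix(c(2, 4, 8), 3))
  expect_equal(as.vector(background_correct(p1, 0.3, 1)$intensities),
               c(1, 2, 6))
  # all values at or below the background clamp to epsilon
  p2 <- make_probes(matrix(c(5, 5, 5), 3))
  expect_equal(as.vector(background_correct(p2, 0.3, 1)$intensities),
               c(1, 1, 1))
  expect_error(background_correct(p1, 0.6), "floor_quantile")
})

test_that("quantile normalization matches the order-statistic mean by hand", {
  p <- make_probes(cbind(c(1, 2, 3), c(4, 5, 6)))
  q <- quantile_normalize(p)
  expect_equal(unname(q$intensities),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- make_probes(cbind(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(quantile_normalize(same)$intensities, same$intensities)
  expect_error(quantile_normalize(make_probes(matrix(1:3, 3))), ">= 2 arrays")
})

test_that("median polish summarization matches the hand decomposition", {
  # 2 probes x 2 arrays, log2 values [[1,2],[3,4]]: overall 2.5, column
  # effects -0.5/+0.5 -> gene log2 values 2 and 3
  m <- 2^matrix(c(1, 3, 2, 4), 2)
  rownames(m) <- c("p1", "p2"); colnames(m) <- c("a1", "a2")
  pt <- probe_table(data.frame(probe_id = c("p1", "p2"),
                               gene_id = c("g", "g"),
                               gc_fraction = c(0.4, 0.6),
                               melting_temp = c(60, 70),
                               position_index = c(0L, 1L)), m)
  es <- summarize_probes(pt)
  expect_equal(unname(log2(es$exprs["g", ])), c(2, 3))

  # single-probe gene passes through; identical probes collapse to them
  m2 <- rbind(p1 = c(8, 16), p2 = c(32, 64), p3 = c(32, 64))
  colnames(m2) <- c("a1", "a2")
  pt2 <- probe_table(data.frame(probe_id = c("p1", "p2", "p3"),
                                gene_id = c("solo", "dup", "dup"),
                                gc_fraction = c(0.4, 0.5, 0.6),
                                melting_temp = c(60, 65, 70),
                                position_index = 0:2), m2)
  es2 <- summarize_probes(pt2)
  expect_equal(unname(es2$exprs["solo", ]), c(8, 16))
  expect_equal(unname(es2$exprs["dup", ]), c(32, 64))
})

test_that("normalization is a no-op without planted bias", {
  sim <- small_cohort(n_genes = 150, seed = 31)
  norm <- covariate_normalize(sim$probes)
  delta <- abs(log2(norm$probes$intensities) - log2(sim$probes$intensities))
  expect_lt(mean(delta), 0.05)
})

test_that("planted covariate bias is removed and equal covariates get equal corrections", {
  genes <- sprintf("G%04d", 1:800)
  sim <- generate_cohort(cohort_config(
    genes, n_per_group = c(NOR = 4, CIR = 4, HCC_EARLY = 4, HCC_LATE = 4),
    baseline_log2_sd = 0.5,
    bias_amplitudes = c(gc = 1, tm = 0, position = 0),
    master_seed = 37))
  biased <- inject_technical_bias(sim$probes, sim$truth)
  pre <- apply(log2(biased$intensities), 2, function(y)
    stats::cor(y, biased$info$gc_fraction, method = "spearman"))
  expect_true(all(abs(pre) >= 0.5))
  norm <- covariate_normalize(biased)
  post <- apply(log2(norm$probes$intensities), 2, function(y)
    stats::cor(y, biased$info$gc_fraction, method = "spearman"))
  expect_true(all(abs(post) < 0.05))

  # probes sharing identical covariate triples receive identical
  # corrections, hence keep their within-array rank order
  set.seed(5)
  n <- 60
  lev <- sample(1:10, n, replace = TRUE)
  m <- matrix(2^rnorm(n * 4, 8), n)
  colnames(m) <- sprintf("a%d", 1:4)
  pt <- probe_table(data.frame(probe_id = sprintf("p%d", 1:n),
                               gene_id = sprintf("g%d", 1:n),
                               gc_fraction = 0.3 + lev / 20,
                               melting_temp = 50 + 2 * lev,
                               position_index = lev),
                    m)
  nm <- covariate_normalize(pt)
  corr <- log2(pt$intensities) - log2(nm$probes$intensities)
  for (a in 1:4) for (l in unique(lev)) {
    expect_lt(diff(range(corr[lev == l, a])), 1e-10)
  }
})

test_that("a constant covariate yields a zero term with a warning", {
  m <- matrix(2^rnorm(120, 8), 60)
  expect_warning(covariate_normalize(make_probes(m, pos = rep(3L, 60))),
                 "constant covariate")
})

test_that("renormalizing normalized output is a near no-op", {
  genes <- sprintf("G%04d", 1:2000)
  sim <- generate_cohort(cohort_config(
    genes, n_per_group = c(NOR = 3, CIR = 3, HCC_EARLY = 3, HCC_LATE = 3),
    baseline_log2_sd = 0.5,
    bias_amplitudes = c(gc = 1, tm = 1, position = 1),
    array_scale_log2_sd = 0.3, master_seed = 41))
  biased <- inject_technical_bias(sim$probes, sim$truth)
  n1 <- covariate_normalize(biased)
  n2 <- covariate_normalize(n1$probes)
  delta <- abs(log2(n2$probes$intensities) - log2(n1$probes$intensities))
  expect_lt(mean(delta), 0.02)
})

test_that("the stored model reproduces its fitted values", {
  sim <- small_cohort(n_genes = 100, seed = 43,
                      bias_amplitudes = c(gc = 0.5, tm = 0, position = 0))
  biased <- inject_technical_bias(sim$probes, sim$truth)
  norm <- covariate_normalize(biased)
  recon <- log2(biased$intensities) - norm$model$fitted
  expect_equal(log2(norm$probes$intensities), recon)
})

test_that("array QC flags a grossly rescaled array and only that array", {
  m <- matrix(rep(2^rnorm(80, 8, 1), 10), 80)
  m[, 4] <- m[, 4] * 10
  p <- make_probes(m)
  expect_equal(qc_flag_arrays(p, cutoff = 0.3), "a4")
  expect_equal(qc_flag_arrays(make_probes(matrix(rep(2^rnorm(40, 8), 5),
                                                 40)), 0.3),
               character(0))
  expect_equal(qc_flag_arrays(p, cutoff = 1.0), character(0))
  expect_error(qc_flag_arrays(make_probes(matrix(1:4, 2)), 0.3), ">= 3")
})
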