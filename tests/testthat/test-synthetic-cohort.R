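test_that("configuration errors name the offending field", {
  g <- c("a", "b")
  expect_error(cohort_config(g, n_per_group = c(NOR = 0, CIR = 1,
                                                HCC_EARLY = 1, HCC_LATE = 1)),
               "n_per_group")
  fx <- matrix(-1, 2, 4, dimnames = list(g, sample_groups()))
  expect_error(cohort_config(g, group_effects = fx), "group_effects")
  expect_error(cohort_config(g, subset_effects = data.frame(
    gene_id = "a", group = "CIR", fraction = 1.2, ratio = 2)), "fraction")
  expect_error(cohort_config(g, noise_log2_sd = -1), "noise_log2_sd")
})

test_that("the study-mimic cohort has the study's sample layout", {
  sim <- mimic_cohort()
  expect_equal(ncol(sim$expr$exprs), 12 + 30 + 31 + 18)
  expect_equal(as.vector(table(sim$expr$groups)), c(12, 30, 31, 18))
  expect_equal(nrow(sim$expr$exprs), 179 + 1399)
})

test_that("identical master seeds give bit-identical cohorts", {
  a <- small_cohort(seed = 11)
  b <- small_cohort(seed = 11)
  c <- small_cohort(seed = 12)
  expect_identical(a$expr$exprs, b$expr$exprs)
  expect_identical(a$probes$intensities, b$probes$intensities)
  expect_identical(a$truth$samples, b$truth$samples)
  expect_false(identical(a$expr$exprs, c$expr$exprs))
})

test_that("zero noise with no subsets reproduces baseline x effect exactly", {
  genes <- c("up", "flat")
  fx <- matrix(1, 2, 4, dimnames = list(genes, sample_groups()))
  fx["up", "CIR"] <- 3
  sim <- generate_cohort(cohort_config(
    genes, n_per_group = c(NOR = 3, CIR = 3, HCC_EARLY = 2, HCC_LATE = 2),
    group_effects = fx, noise_log2_sd = 0, master_seed = 1))
  base <- 2^sim$truth$genes$baseline_log2
  cir <- group_samples(sim$expr, "CIR")
  expect_equal(unname(rowMeans(sim$expr$exprs[, cir])), base * c(3, 1))
  nor <- group_samples(sim$expr, "NOR")
  expect_equal(unname(rowMeans(sim$expr$exprs[, nor])), base)
})

test_that("screen recovers a planted 2x shift at close to oracle power", {
  # oracle power for a plain 2x mean shift (12 NOR vs 30 CIR, sd 0.25,
  # combined t/F at alpha 0.001) by Monte-Carlo with 1e4 reps
  set.seed(421)
  reps <- 1e4
  x <- matrix(rnorm(reps * 30, 1, 0.25), reps)   # log2: shifted group
  y <- matrix(rnorm(reps * 12, 0, 0.25), reps)
  p <- livdevscreen:::row_mean_variance_test(x, y)$p_combined
  power <- mean(p < 0.001)

  genes <- sprintf("G%03d", 1:500)
  fx <- matrix(1, 500, 4, dimnames = list(genes, sample_groups()))
  planted <- genes[1:50]
  fx[planted, "CIR"] <- 2
  sim <- generate_cohort(cohort_config(genes, group_effects = fx,
                                       master_seed = 33))
  de <- screen_gene_set(sim$expr, genes, alpha = 0.001)
  flagged <- sum(de$NOR_CIR_sig[match(planted, de$gene_id)])
  expect_lt(abs(flagged - 50 * power), 3 * sqrt(50 * power * (1 - power)) + 1)
})

test_that("silent gene-groups are indistinguishable across groups", {
  genes <- sprintf("S%02d", 1:60)
  sil <- matrix(TRUE, 60, 4, dimnames = list(genes, sample_groups()))
  sim <- generate_cohort(cohort_config(
    genes, n_per_group = c(NOR = 12, CIR = 12, HCC_EARLY = 12, HCC_LATE = 12),
    silent_flags = sil, master_seed = 9))
  lg <- log2(sim$expr$exprs)
  nor <- group_samples(sim$expr, "NOR"); cir <- group_samples(sim$expr, "CIR")
  p <- vapply(genes, function(g)
    ks_two_sample(lg[g, nor], lg[g, cir])$p_value, 0)
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("a half-fraction subset effect yields a bimodal density", {
  genes <- "bimodal"
  fx <- matrix(1, 1, 4, dimnames = list(genes, sample_groups()))
  fx[1, "HCC_EARLY"] <- 2
  sim <- generate_cohort(cohort_config(
    genes, n_per_group = c(NOR = 4, CIR = 4, HCC_EARLY = 60, HCC_LATE = 4),
    group_effects = fx, noise_log2_sd = 0.2,
    subset_effects = data.frame(gene_id = "bimodal", group = "HCC_EARLY",
                                fraction = 0.5, ratio = 8),
    master_seed = 21))
  d <- density_report(sim$expr, "bimodal", "HCC_EARLY")
  y <- d$density
  # two local maxima separated by a dip
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  big <- peaks[y[peaks] > 0.25 * max(y)]
  expect_gte(length(big), 2)
  expect_gt(abs(d$x[big[length(big)]] - d$x[big[1]]), 1.5)
})

test_that("subset effects preserve the planted group-mean fold-change", {
  genes <- "g"
  fx <- matrix(1, 1, 4, dimnames = list(genes, sample_groups()))
  fx[1, "HCC_EARLY"] <- 2
  sim <- generate_cohort(cohort_config(
    genes, n_per_group = c(NOR = 200, CIR = 4, HCC_EARLY = 2000, HCC_LATE = 4),
    group_effects = fx, noise_log2_sd = 0,
    subset_effects = data.frame(gene_id = "g", group = "HCC_EARLY",
                                fraction = 0.5, ratio = 6),
    master_seed = 3))
  fc <- group_fold_change(sim$expr, "g", "HCC_EARLY")
  expect_equal(fc, 2, tolerance = 0.02)
})

test_that("zero bias amplitudes leave the probe table unchanged", {
  sim <- small_cohort(seed = 5)
  out <- inject_technical_bias(sim$probes, sim$truth)
  expect_equal(out$intensities, sim$probes$intensities)
})

test_that("GC bias of amplitude 1 makes log2 intensity track GC per array", {
  sim <- small_cohort(n_genes = 300, seed = 6, baseline_log2_sd = 0.5,
                      bias_amplitudes = c(gc = 1, tm = 0, position = 0))
  out <- inject_technical_bias(sim$probes, sim$truth)
  rho <- apply(log2(out$intensities), 2, function(y)
    stats::cor(y, out$info$gc_fraction, method = "spearman"))
  expect_true(all(abs(rho) >= 0.5))
  again <- inject_technical_bias(sim$probes, sim$truth)
  expect_identical(out$intensities, again$intensities)
})

test_that("cohort truth serializes losslessly", {
  sim <- small_cohort(seed = 8)
  path <- tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$genes$baseline_log2, sim$truth$genes$baseline_log2)
  expect_equal(back$samples$group, sim$truth$samples$group)
  expect_equal(back$master_seed, sim$truth$master_seed)
})

test_that("summarized probe data matches the gene-level truth without bias", {
  sim <- small_cohort(n_genes = 40, seed = 13)
  es <- summarize_probes(sim$probes)
  err <- abs(log2(es$exprs[rownames(sim$expr$exprs), ]) -
             log2(sim$expr$exprs))
  expect_lt(max(err), 0.1)
})
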