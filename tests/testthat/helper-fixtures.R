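# Shared fixtures.  The study-mimic cohort (master seed 17, the packaged
# study conditions) is generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

mimic_cohort <- function() {
  if (is.null(.fixture_env$mimic))
    .fixture_env$mimic <- generate_cohort(study_mimic_config(master_seed = 17))
  .fixture_env$mimic
}

mimic_registry <- function() {
  if (is.null(.fixture_env$registry))
    .fixture_env$registry <- default_registry()
  .fixture_env$registry
}

# a small clean cohort with a few planted effects, no bias
small_cohort <- function(n_genes = 50, seed = 7, noise = 0.25,
                         n_per_group = c(NOR = 4, CIR = 4,
                                         HCC_EARLY = 4, HCC_LATE = 4),
                         group_effects = NULL, ...) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (!is.null(group_effects)) rownames(group_effects) <- genes
  generate_cohort(cohort_config(
    genes, n_per_group = n_per_group, group_effects = group_effects,
    noise_log2_sd = noise, master_seed = seed, ...))
}

# default gene/sample names for hand-built matrices
named_matrix <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

# hand-built expr_set from a matrix and group labels
make_expr <- function(m, groups) expr_set(named_matrix(m), groups)

# Independent oracle for the exact two-sample K-S p-value: brute-force
# relabeling, with each relabeling's statistic computed by stats::ks.test
# (a code path entirely separate from the package's).  "greater" here
# means x stochastically greater than y, which is ks.test's
# alternative = "less" (CDF of x below that of y).
ks_exact_oracle <- function(x, y, alternative = "two_sided") {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  alt <- if (alternative == "two_sided") "two.sided" else "less"
  stat <- function(idx) {
    suppressWarnings(unname(
      stats::ks.test(pooled[idx], pooled[-idx], alternative = alt)$statistic))
  }
  Dobs <- stat(seq_len(n))
  combs <- utils::combn(n + m, n)
  stats_all <- apply(combs, 2, stat)
  mean(stats_all >= Dobs - 1e-12)
}

# pairwise-concordance AUC oracle with half-credit for ties
auc_concordance_oracle <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# mean silhouette of the NOR samples against all others in a 2-D score
# space (binary clustering: NOR vs rest)
nor_silhouette <- function(scores2d, groups) {
  d <- as.matrix(stats::dist(scores2d))
  nor <- groups == "NOR"
  vals <- vapply(which(nor), function(i) {
    a <- mean(d[i, nor & seq_along(groups) != i])
    b <- mean(d[i, !nor])
    (b - a) / max(a, b)
  }, 0)
  mean(vals)
}
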