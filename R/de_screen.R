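# The differential-expression screen: fold-changes relative to normal,
# Welch t and variance-ratio F tests combined by Fisher's method into a
# single p-value per contrast, a two-sample K-S test, significance calls
# at a fixed alpha (0.001, no multiplicity correction, as in the original
# screen; Benjamini-Hochberg available behind a flag), and classification
# of each gene into an expression-pattern category.
#
# Tests run on log2 values; fold-changes are ratios of linear-scale group
# means.  The combined p-value targets changes in either mean or spread:
# under log-normal expression the sample mean and variance are
# independent, so Fisher's combination of the t and F p-values is
# calibrated.

#' Group fold-change
#'
#' Ratio of arithmetic means of linear-scale expression, group over
#' baseline.
#'
#' @param expr An \code{expr_set}.
#' @param gene Gene id.
#' @param group Group label (or \code{"HCC"} for the pooled tumor set).
#' @param baseline Baseline group label (default \code{"NOR"}).
#' @return The fold-change (positive real).
#' @export
group_fold_change <- function(expr, gene, group, baseline = "NOR") {
  if (!gene %in% rownames(expr$exprs)) stopf("gene '%s' not in matrix", gene)
  g <- expr$exprs[gene, group_samples(expr, group)]
  b <- expr$exprs[gene, group_samples(expr, baseline)]
  if (!length(g) || !length(b)) stopf("both groups must be non-empty")
  mb <- mean(b)
  if (mb <= 0) stopf("baseline mean must be positive")
  mean(g) / mb
}

# Vectorised Welch t, variance-ratio F and Fisher-combined p-values for
# every row of log2 matrices x (n columns) vs y (m columns).
row_mean_variance_test <- function(x, y) {
  n <- ncol(x); m <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1)
  vy <- rowSums((y - my)^2) / (m - 1)
  se2 <- vx / n + vy / m
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / m)^2 / (m - 1))
  p_t <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p_t[se2 == 0] <- 1                      # identical constant samples

  f <- vx / vy
  p_low <- stats::pf(f, n - 1, m - 1)
  p_f <- 2 * pmin(p_low, 1 - p_low)
  both_const <- vx == 0 & vy == 0
  if (any(both_const)) {
    warnf("%d gene(s) with zero variance in both samples: p_f set to 1",
          sum(both_const))
    p_f[both_const] <- 1
  }
  p_f[vx == 0 & vy > 0] <- 2 * stats::pf(0, n - 1, m - 1)
  p_f <- pmin(p_f, 1)

  X <- -2 * (log(p_t) + log(p_f))
  p_comb <- stats::pchisq(X, df = 4, lower.tail = FALSE)
  data.frame(p_t = p_t, p_f = p_f, p_combined = p_comb)
}

#' Combined mean-variance test
#'
#' Two-sided Welch t test (mean shift) and two-sided variance-ratio F test
#' (spread change) on log2 values, combined into one p-value by Fisher's
#' method: X = -2(ln p_t + ln p_f) referred to chi-square with 4 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of log2 expression values (each length >= 2).
#' @return List with \code{p_t}, \code{p_f} and \code{p_combined}.
#' @export
mean_variance_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("both samples need >= 2 values")
  r <- row_mean_variance_test(matrix(x, 1), matrix(y, 1))
  list(p_t = r$p_t, p_f = r$p_f, p_combined = r$p_combined)
}

.contrast_defs <- function() list(
  NOR_CIR    = c("NOR", "CIR"),
  NOR_EARLY  = c("NOR", "HCC_EARLY"),
  NOR_LATE   = c("NOR", "HCC_LATE"),
  CIR_EARLY  = c("CIR", "HCC_EARLY"),
  CIR_LATE   = c("CIR", "HCC_LATE"),
  CIR_HCC    = c("CIR", "HCC"),
  EARLY_LATE = c("HCC_EARLY", "HCC_LATE"))

#' Screen a gene set for differential expression
#'
#' For each gene computes, per contrast, the linear fold-change (second
#' group over first), the Welch t, variance-F, Fisher-combined and
#' two-sample K-S p-values (log2 scale), and a significance flag at
#' \code{alpha} on the combined p-value.  Contrasts: NOR vs CIR, NOR vs
#' each tumor stage, CIR vs each tumor stage, CIR vs pooled HCC, and early
#' vs late.  A \code{pattern} column classifies each gene (see
#' \code{\link{classify_pattern}}).
#'
#' @param expr An \code{expr_set} with group labels.
#' @param genes Gene ids to screen; unknown ids are skipped with a warning.
#' @param alpha Significance threshold on the combined p-value.
#' @param adjust \code{"none"} (fixed alpha, as in the original screen) or
#'   \code{"BH"} for Benjamini-Hochberg adjustment of the combined
#'   p-values within each contrast before flagging.
#' @return Data frame of class \code{de_result}, one row per gene, with
#'   columns \code{<contrast>_fc}, \code{_p_t}, \code{_p_f}, \code{_p_comb},
#'   \code{_p_ks}, \code{_sig} per contrast and a final \code{pattern}.
#' @export
screen_gene_set <- function(expr, genes, alpha = 0.001,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(expr$groups)) stopf("expression set has no group labels")
  missing <- setdiff(genes, rownames(expr$exprs))
  if (length(missing)) {
    warnf("skipping %d gene(s) not in the matrix: %s", length(missing),
          paste(utils::head(missing, 5), collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) stopf("no genes to screen")
  lin <- expr$exprs[genes, , drop = FALSE]
  lg <- log2(lin)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cn in names(.contrast_defs())) {
    cdef <- .contrast_defs()[[cn]]
    sa <- group_samples(expr, cdef[1])
    sb <- group_samples(expr, cdef[2])
    fc <- rowMeans(lin[, sb, drop = FALSE]) / rowMeans(lin[, sa, drop = FALSE])
    tests <- row_mean_variance_test(lg[, sb, drop = FALSE],
                                    lg[, sa, drop = FALSE])
    p_ks <- vapply(genes, function(g) {
      D <- ks_statistic(lg[g, sb], lg[g, sa], "two_sided")
      ks_p_asymptotic(D, length(sb), length(sa), "two_sided")
    }, 0)
    p_flag <- if (adjust == "BH") stats::p.adjust(tests$p_combined, "BH")
              else tests$p_combined
    out[[paste0(cn, "_fc")]] <- unname(fc)
    out[[paste0(cn, "_p_t")]] <- tests$p_t
    out[[paste0(cn, "_p_f")]] <- tests$p_f
    out[[paste0(cn, "_p_comb")]] <- tests$p_combined
    out[[paste0(cn, "_p_ks")]] <- unname(p_ks)
    out[[paste0(cn, "_sig")]] <- p_flag < alpha
  }
  out$pattern <- vapply(seq_len(nrow(out)), function(i)
    classify_pattern(out[i, ]), "")
  class(out) <- c("de_result", "data.frame")
  out
}

#' Classify a gene's expression pattern
#'
#' Decision rules over the screened contrasts:
#' \itemize{
#' \item \code{CIR_PEAK}: up in cirrhosis (significant NOR vs CIR, fc > 1)
#'   with a significant decline from cirrhosis into tumors.
#' \item \code{DOWN_PERSISTENT}: down in cirrhosis and no significant
#'   change from cirrhosis into tumors.
#' \item \code{TUMOR_ONLY}: unchanged in cirrhosis, significant in the
#'   tumors (early stage, with or without late).
#' \item \code{LATE_ONLY}: significant only in late-stage tumors.
#' \item \code{SHARED_AMPLIFIED}: significant in cirrhosis and tumors with
#'   strictly larger |log2 fc| in tumors; ties fall to
#'   \code{SHARED_SIMILAR}.
#' \item \code{SHARED_SIMILAR}: significant in cirrhosis and tumors
#'   otherwise.
#' \item \code{UNCHANGED}: nothing significant.
#' }
#'
#' @param r One row of a \code{de_result}.
#' @param alpha Unused when the row carries \code{_sig} flags (kept for a
#'   row built by hand from p-values).
#' @return A pattern label string.
#' @export
classify_pattern <- function(r, alpha = 0.001) {
  sigC <- isTRUE(r$NOR_CIR_sig); sigE <- isTRUE(r$NOR_EARLY_sig)
  sigL <- isTRUE(r$NOR_LATE_sig); sigCH <- isTRUE(r$CIR_HCC_sig)
  fc_cir <- r$NOR_CIR_fc
  # pooled tumor fc vs normal, from the stage fold-changes is not directly
  # available; use the CIR_HCC contrast direction: tumor vs cirrhosis
  if (!sigC && !sigE && !sigL) return("UNCHANGED")
  if (!sigC) {
    if (sigE) return("TUMOR_ONLY")
    return("LATE_ONLY")
  }
  tumor_vs_cir_fc <- r$CIR_HCC_fc
  if (fc_cir > 1 && sigCH && tumor_vs_cir_fc < 1) return("CIR_PEAK")
  if (fc_cir < 1 && !sigCH) return("DOWN_PERSISTENT")
  if (sigE || sigL) {
    fc_tumor <- fc_cir * tumor_vs_cir_fc   # tumor vs normal
    if (abs(log2(fc_tumor)) > abs(log2(fc_cir))) return("SHARED_AMPLIFIED")
    return("SHARED_SIMILAR")
  }
  "SHARED_SIMILAR"
}
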