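# Discrimination machinery: scaled PCA on functional gene sets, projection
# of an independent cohort with the training loadings, and leave-one-out
# cross-validated ROC of the marker-panel score.

#' Fit a scaled PCA on a gene set
#'
#' Centers and unit-variance scales each gene's log2 values, then
#' eigen-decomposes the sample covariance (prcomp with scaling).
#' Zero-variance genes are dropped with a warning.  Loading signs follow a
#' fixed convention: each loading's largest-magnitude element is positive.
#'
#' @param expr An \code{expr_set}.
#' @param genes Gene ids to use (>= 2 usable, >= 3 samples).
#' @return A \code{pca_model}: \code{genes}, \code{center}, \code{scale}
#'   (log2 space), \code{loadings} (genes x components),
#'   \code{explained} (variance fractions), \code{scores} (training
#'   samples x components) and the training groups.
#' @export
pca_fit <- function(expr, genes) {
  miss <- setdiff(genes, rownames(expr$exprs))
  if (length(miss)) stopf("gene(s) not in matrix: %s", paste(miss, collapse = ", "))
  lg <- t(log2(expr$exprs[genes, , drop = FALSE]))   # samples x genes
  if (nrow(lg) < 3) stopf("scaled PCA needs >= 3 samples")
  v <- apply(lg, 2, stats::var)
  if (any(v == 0)) {
    warnf("dropping %d zero-variance gene(s): %s", sum(v == 0),
          paste(genes[v == 0], collapse = ", "))
    genes <- genes[v > 0]
    lg <- lg[, v > 0, drop = FALSE]
  }
  if (length(genes) < 2) stopf("scaled PCA needs >= 2 genes with variance")
  pc <- stats::prcomp(lg, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| element positive
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  structure(list(
    genes = genes,
    center = pc$center, scale = pc$scale,
    loadings = pc$rotation,
    explained = pc$sdev^2 / sum(pc$sdev^2),
    scores = pc$x,
    groups = expr$groups), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d genes, %d samples; PC1/PC2 explain %.1f%% / %.1f%%\n",
              length(x$genes), nrow(x$scores),
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Project a cohort onto trained PCA loadings
#'
#' Standardizes the new cohort's log2 values per gene with the new
#' cohort's own center and scale (absorbing cross-platform shifts), then
#' multiplies by the training loadings.  Projecting the training matrix
#' with its own model reproduces the training scores exactly.
#'
#' @param model A \code{pca_model}.
#' @param expr An \code{expr_set} containing all model genes.
#' @return Matrix of per-sample score vectors (samples x components).
#' @export
pca_project <- function(model, expr) {
  miss <- setdiff(model$genes, rownames(expr$exprs))
  if (length(miss)) stopf("model gene(s) missing from matrix: %s",
                          paste(miss, collapse = ", "))
  lg <- t(log2(expr$exprs[model$genes, , drop = FALSE]))
  z <- scale(lg, center = TRUE, scale = TRUE)
  z %*% model$loadings
}

# trapezoid AUC over the (FPR, TPR) curve traced by sweeping thresholds;
# equivalent to pairwise concordance with a half-credit tie correction.
roc_points <- function(score, truth) {
  thr <- sort(unique(score), decreasing = TRUE)
  thr <- c(Inf, thr)
  sens <- vapply(thr, function(t) mean(score[truth] >= t), 0)
  spec <- vapply(thr, function(t) mean(score[!truth] < t), 0)
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

auc_trapezoid <- function(score, truth) {
  rp <- roc_points(score, truth)
  fpr <- 1 - rp$specificity
  sum(diff(fpr) * (utils::head(rp$sensitivity, -1) +
                   utils::tail(rp$sensitivity, -1)) / 2)
}

#' Leave-one-out cross-validated ROC
#'
#' Each sample's score is computed with the training fold only: the score
#' is the maximum per-sample fold-change over the gene set, with the
#' baseline mean taken over the training fold's NOR samples (no
#' information leak).  A \code{"pc1"} variant scores each held-out sample
#' by its projection on the first component of a scaled PCA fitted on the
#' training fold.  Thresholds sweep the observed scores; AUC by trapezoid;
#' the operating point maximizes Youden's J (sensitivity + specificity - 1).
#'
#' @param expr An \code{expr_set} with group labels.
#' @param genes Gene set used for scoring.
#' @param tumor_groups Groups counted as positives, default both tumor
#'   stages.
#' @param score \code{"max_fc"} (default, the panel statistic) or
#'   \code{"pc1"}.
#' @param threshold Fold-change threshold used only to report the panel
#'   rule's own operating point (default 1.5).
#' @return A \code{roc_report}: per-fold scores and labels, ROC table,
#'   \code{auc}, and the Youden-optimal \code{sensitivity} /
#'   \code{specificity}.
#' @export
loocv_roc <- function(expr, genes, tumor_groups = c("HCC_EARLY", "HCC_LATE"),
                      score = c("max_fc", "pc1"), threshold = 1.5) {
  score <- match.arg(score)
  if (is.null(expr$groups)) stopf("expression set has no group labels")
  tumor_groups <- expand_group_alias(tumor_groups)
  truth <- expr$groups %in% tumor_groups
  if (!any(truth) || all(truth)) stopf("need samples in both classes")
  nor_ids <- group_samples(expr, "NOR")
  n <- ncol(expr$exprs)
  ids <- colnames(expr$exprs)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    train_nor <- setdiff(nor_ids, ids[i])
    if (score == "max_fc") {
      base <- rowMeans(expr$exprs[genes, train_nor, drop = FALSE])
      scores[i] <- max(expr$exprs[genes, ids[i]] / base)
    } else {
      train <- expr_set(expr$exprs[, -i, drop = FALSE], expr$groups[-i])
      fit <- pca_fit(train, genes)
      lg <- log2(expr$exprs[fit$genes, ids[i]])
      z <- (lg - fit$center) / fit$scale
      scores[i] <- sum(z * fit$loadings[, 1])
    }
  }
  rp <- roc_points(scores, truth)
  auc <- auc_trapezoid(scores, truth)
  j <- rp$sensitivity + rp$specificity - 1
  best <- which.max(j)
  structure(list(
    folds = data.frame(sample_id = ids, score = scores, tumor = truth,
                       stringsAsFactors = FALSE),
    roc = rp, auc = auc,
    sensitivity = rp$sensitivity[best],
    specificity = rp$specificity[best],
    youden_threshold = rp$threshold[best],
    score_type = score, fc_threshold = threshold), class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf(
    "roc_report (%s, LOOCV, %d folds): AUC %.3f; sens %.1f%% / spec %.1f%%\n",
    x$score_type, nrow(x$folds), x$auc,
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
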