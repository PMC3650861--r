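# Marker-panel coverage: the "at least one panel gene with per-sample
# fold-change > 1.5 vs the normal-group mean" rule, plus a greedy
# set-cover search for candidate panels.

#' Per-sample fold-change vs a baseline group
#'
#' One sample's linear expression value divided by the arithmetic mean of
#' the baseline group's values for that gene.
#'
#' @param expr An \code{expr_set}.
#' @param gene Gene id.
#' @param sample Sample id.
#' @param baseline_group Baseline group, default \code{"NOR"}.
#' @return The fold-change.
#' @export
per_sample_fold_change <- function(expr, gene, sample, baseline_group = "NOR") {
  if (!gene %in% rownames(expr$exprs)) stopf("gene '%s' not in matrix", gene)
  if (!sample %in% colnames(expr$exprs)) stopf("sample '%s' not in matrix", sample)
  b <- mean(expr$exprs[gene, group_samples(expr, baseline_group)])
  if (b <= 0) stopf("baseline mean must be positive")
  expr$exprs[gene, sample] / b
}

# fold-change matrix: panel genes x target samples, vs baseline-group mean
panel_fc_matrix <- function(expr, panel, target_samples, baseline_group) {
  miss <- setdiff(panel, rownames(expr$exprs))
  if (length(miss)) stopf("panel gene(s) not in matrix: %s",
                          paste(miss, collapse = ", "))
  base_mean <- rowMeans(expr$exprs[panel,
                                   group_samples(expr, baseline_group),
                                   drop = FALSE])
  sweep(expr$exprs[panel, target_samples, drop = FALSE], 1, base_mean, "/")
}

#' Panel coverage report
#'
#' A target sample is covered when at least one panel gene exceeds the
#' fold-change threshold (strict \code{>}) relative to the baseline-group
#' mean.  Coverage is the fraction of covered target samples.
#'
#' @param expr An \code{expr_set}.
#' @param panel Gene ids of the panel (non-empty).
#' @param target_samples Sample ids to cover, or a group label / alias
#'   such as \code{"HCC"}.
#' @param threshold Fold-change threshold (strict), default 1.5.
#' @param baseline_group Baseline group, default \code{"NOR"}.
#' @return A \code{panel_report}: \code{per_sample} data frame
#'   (\code{sample_id}, \code{max_fc}, \code{argmax_gene}, \code{covered}),
#'   \code{coverage}, plus the panel and threshold used.
#' @export
panel_coverage <- function(expr, panel, target_samples, threshold = 1.5,
                           baseline_group = "NOR") {
  if (!length(panel)) stopf("panel must be non-empty")
  if (length(target_samples) == 1 &&
      target_samples %in% c(sample_groups(), "HCC"))
    target_samples <- group_samples(expr, target_samples)
  if (!length(target_samples)) stopf("target samples must be non-empty")
  fc <- panel_fc_matrix(expr, panel, target_samples, baseline_group)
  max_i <- apply(fc, 2, which.max)
  per_sample <- data.frame(
    sample_id = colnames(fc),
    max_fc = apply(fc, 2, max),
    argmax_gene = panel[max_i],
    stringsAsFactors = FALSE)
  per_sample$covered <- per_sample$max_fc > threshold
  structure(list(panel = panel, threshold = threshold,
                 baseline_group = baseline_group,
                 per_sample = per_sample,
                 coverage = mean(per_sample$covered)),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("panel_report: {%s} at FC > %g covers %.1f%% of %d samples\n",
              paste(x$panel, collapse = ", "), x$threshold,
              100 * x$coverage, nrow(x$per_sample)))
  invisible(x)
}

#' Greedy marker-panel search
#'
#' Greedy set cover: iteratively adds the candidate gene covering the most
#' still-uncovered target samples (ties broken lexicographically by gene
#' id), stopping at full coverage or \code{max_size} genes.
#'
#' @param expr An \code{expr_set}.
#' @param candidates Candidate gene ids (non-empty).
#' @param target_samples Sample ids (or group label) to cover.
#' @param threshold Fold-change threshold (strict).
#' @param max_size Maximum panel size.
#' @param baseline_group Baseline group, default \code{"NOR"}.
#' @return Character vector: the selected panel (possibly achieving only
#'   partial coverage).
#' @export
greedy_panel_search <- function(expr, candidates, target_samples,
                                threshold = 1.5, max_size = 4,
                                baseline_group = "NOR") {
  if (!length(candidates)) stopf("candidates must be non-empty")
  if (length(target_samples) == 1 &&
      target_samples %in% c(sample_groups(), "HCC"))
    target_samples <- group_samples(expr, target_samples)
  if (!length(target_samples)) {
    warnf("empty target sample set: returning an empty panel")
    return(character(0))
  }
  fc <- panel_fc_matrix(expr, candidates, target_samples, baseline_group)
  covers <- fc > threshold            # candidate x sample
  panel <- character(0)
  uncovered <- rep(TRUE, ncol(covers))
  remaining <- candidates[order(candidates)]
  while (length(panel) < max_size && any(uncovered) && length(remaining)) {
    gains <- vapply(remaining, function(g)
      sum(covers[g, uncovered, drop = FALSE]), 0L)
    if (max(gains) == 0L) break
    best <- remaining[which.max(gains)]   # first in lexicographic order
    panel <- c(panel, best)
    uncovered <- uncovered & !covers[best, ]
    remaining <- setdiff(remaining, best)
  }
  panel
}
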