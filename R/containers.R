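# Lightweight S3 containers used across the pipeline.
#
# expr_set:    gene x sample matrix of linear-scale expression plus a group
#              factor for the samples.  All screens operate on this.
# probe_table: probe-level intensities plus the technical covariates
#              (GC fraction, melting temperature, transcript position) that
#              the covariate-regression normalization fits against.

#' Construct a gene-level expression set
#'
#' @param exprs Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); values on the linear intensity
#'   scale, strictly positive.
#' @param groups Factor or character vector of group labels (one of
#'   \code{\link{sample_groups}()}), one per column of \code{exprs}; may be
#'   NULL for matrices whose grouping is supplied later (the screens all
#'   require groups).
#' @return An object of class \code{expr_set}.
#' @export
expr_set <- function(exprs, groups = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stopf("'exprs' must be a numeric matrix")
  if (is.null(rownames(exprs)) || anyDuplicated(rownames(exprs)))
    stopf("'exprs' must have unique rownames (gene ids)")
  if (is.null(colnames(exprs)) || anyDuplicated(colnames(exprs)))
    stopf("'exprs' must have unique colnames (sample ids)")
  if (!is.null(groups)) {
    if (length(groups) != ncol(exprs))
      stopf("'groups' must have one label per sample (%d != %d)",
            length(groups), ncol(exprs))
    groups <- as.character(groups)
    bad <- setdiff(unique(groups), sample_groups())
    if (length(bad))
      stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
    groups <- factor(groups, levels = sample_groups())
    names(groups) <- colnames(exprs)
  }
  structure(list(exprs = exprs, groups = groups), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples\n", nrow(x$exprs), ncol(x$exprs)))
  if (!is.null(x$groups)) print(table(x$groups))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$exprs)

#' Subset an expression set to samples of given groups
#'
#' @param x An \code{expr_set}.
#' @param groups Group labels to keep; \code{"HCC"} expands to both tumor
#'   stages.
#' @return An \code{expr_set} restricted to the matching samples.
#' @export
subset_groups <- function(x, groups) {
  groups <- expand_group_alias(groups)
  keep <- x$groups %in% groups
  if (!any(keep)) stopf("no samples in group(s) %s", paste(groups, collapse = ", "))
  expr_set(x$exprs[, keep, drop = FALSE], x$groups[keep])
}

# "HCC" is the pooled tumor set (both stages).
expand_group_alias <- function(groups) {
  out <- unlist(lapply(groups, function(g) {
    if (identical(g, "HCC")) c("HCC_EARLY", "HCC_LATE") else g
  }))
  bad <- setdiff(out, sample_groups())
  if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  unique(out)
}

#' Sample ids belonging to given groups
#'
#' @param x An \code{expr_set}.
#' @param groups Group labels; \code{"HCC"} expands to both tumor stages.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(x, groups) {
  names(x$groups)[x$groups %in% expand_group_alias(groups)]
}

log2_exprs <- function(x) log2(x$exprs)

#' Construct a probe-level intensity table
#'
#' @param info Data frame with columns \code{probe_id}, \code{gene_id},
#'   \code{gc_fraction} (in [0,1]), \code{melting_temp} (degrees C) and
#'   \code{position_index} (0-based offset along the transcript).
#' @param intensities Numeric matrix, one row per probe (same order as
#'   \code{info}), one column per sample; strictly positive linear-scale
#'   values.
#' @param groups Optional group labels for the samples (kept for
#'   convenience when summarizing straight to an \code{expr_set}).
#' @return An object of class \code{probe_table}.
#' @export
probe_table <- function(info, intensities, groups = NULL) {
  need <- c("probe_id", "gene_id", "gc_fraction", "melting_temp", "position_index")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stopf("probe info is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(info$probe_id)) stopf("duplicate probe_id values")
  if (any(info$gc_fraction < 0 | info$gc_fraction > 1))
    stopf("gc_fraction must lie in [0, 1]")
  if (any(info$position_index < 0)) stopf("position_index must be >= 0")
  if (!is.matrix(intensities) || nrow(intensities) != nrow(info))
    stopf("'intensities' must be a matrix with one row per probe")
  if (is.null(colnames(intensities)) || anyDuplicated(colnames(intensities)))
    stopf("'intensities' must have unique sample ids as colnames")
  rownames(intensities) <- info$probe_id
  if (!is.null(groups)) {
    groups <- factor(as.character(groups), levels = sample_groups())
    names(groups) <- colnames(intensities)
  }
  structure(list(info = as.data.frame(info, stringsAsFactors = FALSE),
                 intensities = intensities, groups = groups),
            class = "probe_table")
}

#' @export
print.probe_table <- function(x, ...) {
  cat(sprintf("probe_table: %d probes (%d genes) x %d arrays\n",
              nrow(x$intensities), length(unique(x$info$gene_id)),
              ncol(x$intensities)))
  invisible(x)
}

#' @export
dim.probe_table <- function(x) dim(x$intensities)
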