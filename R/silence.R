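# Silent-gene screens: is a gene expressed above the background of
# never-expressed genes, and do liver genes differ in distribution from
# their non-liver paralogs within tumors?

#' Build the pooled background model
#'
#' Pools all log2 values of the silent-registry genes across the stated
#' reference samples into one empirical distribution.  Genes with zero
#' expression evidence in normal liver define what "not expressed" looks
#' like on this platform, so their normal-liver values are the natural
#' null for the expressed-above-background call.
#'
#' @param expr An \code{expr_set}.
#' @param registry A \code{gene_registry} (its \code{silent} set is used)
#'   or a character vector of background gene ids.
#' @param groups Reference group(s), default \code{"NOR"}.
#' @return A \code{background_model}: sorted pooled log2 values.
#' @export
build_background <- function(expr, registry, groups = "NOR") {
  genes <- if (inherits(registry, "gene_registry")) registry$silent else registry
  genes <- intersect(genes, rownames(expr$exprs))
  if (length(genes) < 20)
    stopf("background needs >= 20 registry genes present (have %d)",
          length(genes))
  samples <- group_samples(expr, groups)
  if (!length(samples)) stopf("empty group selection for the background")
  vals <- sort(as.vector(log2(expr$exprs[genes, samples, drop = FALSE])))
  structure(list(values = vals, n_genes = length(genes),
                 groups = expand_group_alias(groups)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: %d pooled values from %d genes (%s)\n",
              length(x$values), x$n_genes, paste(x$groups, collapse = ",")))
  invisible(x)
}

#' Background quantiles
#'
#' @param x A \code{background_model}.
#' @param probs Quantile probabilities.
#' @return Quantiles of the pooled background (log2 scale).
#' @export
background_quantile <- function(x, probs) stats::quantile(x$values, probs)

#' Call a gene expressed above background
#'
#' One-sided two-sample K-S test of the gene's values in the stated group
#' against the pooled background, alternative: the gene's distribution is
#' stochastically greater.  Expression can only raise intensity above
#' background, hence the one-sided form.
#'
#' @param expr An \code{expr_set}.
#' @param gene Gene id.
#' @param group Group label (or \code{"HCC"} for pooled tumors).
#' @param background A \code{background_model}.
#' @param alpha Call threshold.
#' @return List with \code{expressed} (logical) and \code{p}.
#' @export
call_expressed <- function(expr, gene, group, background, alpha = 0.001) {
  if (!gene %in% rownames(expr$exprs)) stopf("gene '%s' not in matrix", gene)
  vals <- log2(expr$exprs[gene, group_samples(expr, group)])
  D <- ks_statistic(vals, background$values, "greater")
  p <- ks_p_asymptotic(D, length(vals), length(background$values), "greater")
  list(expressed = p < alpha, p = p)
}

#' Run the expressed-above-background screen over a registry
#'
#' @param expr An \code{expr_set}.
#' @param registry A \code{gene_registry} or character vector of genes to
#'   test (defaults to the registry's silent set).
#' @param group Group to test, default pooled \code{"HCC"}.
#' @param background Background model; built from the registry's silent
#'   genes in NOR when missing.
#' @param alpha Call threshold.
#' @return Data frame with \code{gene_id}, \code{p}, \code{expressed}.
#' @export
silence_screen <- function(expr, registry, group = "HCC",
                           background = NULL, alpha = 0.001) {
  genes <- if (inherits(registry, "gene_registry")) registry$silent else registry
  genes <- intersect(genes, rownames(expr$exprs))
  if (is.null(background)) background <- build_background(expr, genes, "NOR")
  samples <- group_samples(expr, group)
  lg <- log2(expr$exprs[genes, samples, drop = FALSE])
  p <- vapply(seq_along(genes), function(i) {
    D <- ks_statistic(lg[i, ], background$values, "greater")
    ks_p_asymptotic(D, ncol(lg), length(background$values), "greater")
  }, 0)
  data.frame(gene_id = genes, p = p, expressed = p < alpha,
             stringsAsFactors = FALSE)
}

#' Liver-gene vs paralog distribution contrast
#'
#' Two-sided two-sample K-S test between a liver gene's and its paralog's
#' expression distributions within one sample group.
#'
#' @param expr An \code{expr_set}.
#' @param pair Character vector \code{c(liver_gene, paralog_gene)}.
#' @param group Group label, default pooled \code{"HCC"}.
#' @param alpha Call threshold.
#' @return List with \code{different} (logical), \code{p} and \code{D}.
#' @export
paralog_contrast <- function(expr, pair, group = "HCC", alpha = 0.001) {
  miss <- setdiff(pair, rownames(expr$exprs))
  if (length(miss)) stopf("gene(s) not in matrix: %s", paste(miss, collapse = ", "))
  samples <- group_samples(expr, group)
  a <- log2(expr$exprs[pair[1], samples])
  b <- log2(expr$exprs[pair[2], samples])
  ks <- ks_two_sample(a, b, "two_sided")
  list(different = ks$p_value < alpha, p = ks$p_value, D = ks$statistic)
}

#' Screen all registry paralog pairs
#'
#' @param expr An \code{expr_set}.
#' @param registry A \code{gene_registry} (its \code{paralog_pairs} are
#'   used) or a data frame with \code{liver_gene}, \code{paralog_gene}.
#' @param group Group label, default pooled \code{"HCC"}.
#' @param alpha Call threshold.
#' @return Data frame: pair columns plus \code{D}, \code{p},
#'   \code{different}.
#' @export
paralog_screen <- function(expr, registry, group = "HCC", alpha = 0.001) {
  pairs <- if (inherits(registry, "gene_registry")) registry$paralog_pairs
           else registry
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- paralog_contrast(expr,
                          c(pairs$liver_gene[i], pairs$paralog_gene[i]),
                          group, alpha)
    data.frame(liver_gene = pairs$liver_gene[i],
               paralog_gene = pairs$paralog_gene[i],
               D = r$D, p = r$p, different = r$different,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Kernel density tables per gene and group
#'
#' Gaussian-kernel densities of log2 expression (Silverman's rule
#' bandwidth) tabulated on 256 grid points, plotting-ready.
#'
#' @param expr An \code{expr_set}.
#' @param genes Gene ids.
#' @param groups Group labels (aliases like \code{"HCC"} allowed).
#' @return Long data frame: \code{gene_id}, \code{group}, \code{x},
#'   \code{density}.
#' @export
density_report <- function(expr, genes, groups) {
  miss <- setdiff(genes, rownames(expr$exprs))
  if (length(miss)) stopf("gene(s) not in matrix: %s", paste(miss, collapse = ", "))
  out <- list()
  for (g in genes) for (grp in groups) {
    vals <- log2(expr$exprs[g, group_samples(expr, grp)])
    d <- if (stats::sd(vals) == 0) {
      # degenerate sample: a narrow spike at the common value
      stats::density(vals, bw = 1e-3, n = 256, cut = 5)
    } else {
      stats::density(vals, bw = "nrd0", n = 256)
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g, group = grp, x = d$x, density = d$y,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
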