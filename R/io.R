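# Readers and writers.  TSV is the canonical matrix format (genes/probes
# in rows, samples in columns, sidecar TSV mapping sample to group);
# GEO Series-Matrix text is supported read-only for validation cohorts.

#' Write a gene-level expression matrix as TSV
#'
#' @param expr An \code{expr_set}.
#' @param path Output TSV (first column \code{gene_id}, then sample ids).
#' @param groups_path Optional sidecar TSV (\code{sample_id}, \code{group});
#'   written when the set has group labels.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(expr, path, groups_path = NULL) {
  df <- data.frame(gene_id = rownames(expr$exprs), expr$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path) && !is.null(expr$groups)) {
    utils::write.table(
      data.frame(sample_id = names(expr$groups),
                 group = as.character(expr$groups)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene-level expression matrix from TSV
#'
#' @param path TSV written by \code{\link{write_expression_tsv}}.
#' @param groups_path Optional sidecar TSV of sample groups.
#' @return An \code{expr_set}.
#' @export
read_expression_tsv <- function(path, groups_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stopf("expected first column 'gene_id'")
  if (anyDuplicated(df$gene_id))
    stopf("duplicate gene id: %s", df$gene_id[duplicated(df$gene_id)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)[1, ]
    stopf("non-numeric cell at row %d, column %d", bad[1], bad[2] + 1L)
  }
  rownames(m) <- df$gene_id
  groups <- NULL
  if (!is.null(groups_path)) {
    gdf <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
    groups <- gdf$group[match(colnames(m), gdf$sample_id)]
    if (anyNA(groups)) stopf("groups sidecar misses sample(s)")
  }
  expr_set(m, groups)
}

#' Write a probe table as TSV
#'
#' Columns: \code{probe_id, gene_id, gc_fraction, melting_temp,
#' position_index}, then one column per sample.  \code{position_index} is
#' a 0-based offset along the transcript.
#'
#' @param probes A \code{probe_table}.
#' @param path Output TSV.
#' @param groups_path Optional sidecar TSV of sample groups.
#' @return \code{path}, invisibly.
#' @export
write_probe_tsv <- function(probes, path, groups_path = NULL) {
  df <- cbind(probes$info, as.data.frame(probes$intensities,
                                         check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path) && !is.null(probes$groups)) {
    utils::write.table(
      data.frame(sample_id = colnames(probes$intensities),
                 group = as.character(probes$groups)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a probe table from TSV
#'
#' @param path TSV written by \code{\link{write_probe_tsv}}.
#' @param groups_path Optional sidecar TSV of sample groups.
#' @return A \code{probe_table}.
#' @export
read_probe_tsv <- function(path, groups_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("probe_id", "gene_id", "gc_fraction", "melting_temp",
            "position_index")
  miss <- setdiff(meta, names(df))
  if (length(miss)) stopf("probe TSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  groups <- NULL
  if (!is.null(groups_path)) {
    gdf <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
    groups <- gdf$group[match(colnames(m), gdf$sample_id)]
  }
  probe_table(df[meta], m, groups)
}

#' Read a GEO Series-Matrix text file
#'
#' Parses the table between \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end}; quoted identifiers are unquoted, and
#' the \code{!}-prefixed metadata lines are preserved in a provenance
#' attribute.
#'
#' @param path Series-Matrix text file.
#' @return An \code{expr_set} (no group labels) with attribute
#'   \code{"provenance"} holding the metadata lines.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg)
    stopf("missing or malformed series-matrix table delimiters")
  meta <- grep("^!", lines[-(beg:end)], value = TRUE)
  tab <- utils::read.delim(text = lines[(beg + 1):(end - 1)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- gsub('^"|"$', "", as.character(tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  colnames(m) <- gsub('^"|"$', "", colnames(tab)[-1])
  out <- expr_set(m, NULL)
  attr(out, "provenance") <- meta
  out
}

#' Write a DE screen result as TSV
#'
#' @param de A \code{de_result} data frame.
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
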