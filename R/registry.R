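# Gene-set registry: the curated sets the screens run over.
#
# The packaged default mirrors the liver-development gene lists printed in
# the study tables and body text.  The full 179-gene curation and the full
# 1,399-gene never-expressed-in-liver list are not printed anywhere, so the
# remaining slots are filled with clearly-labelled synthetic placeholders
# (LIVDEV_*, PARA_*, SILENT_*) that carry the same planted statistical
# behaviour; users can swap in their own curation via read_registry().

# Cirrhosis-peak genes with their printed mean fold-changes vs normal
# (cirrhosis / early HCC / late HCC).
.cir_peak_fc <- function() {
  m <- matrix(c(
    14.8, 14.0, 5.7,   # EPCAM
     7.5,  6.1, 3.5,   # MMP7
     6.0,  2.9, 1.8,   # KRT19
     5.4,  4.8, 3.0,   # MMP2
     5.8,  5.2, 4.8,   # VIM
     4.9,  3.2, 2.9,   # SOX9
     4.4,  2.3, 1.9,   # LAMA2
     4.3,  2.4, 1.8,   # FGFR2
     3.9,  2.6, 1.8,   # KLF6
     3.9,  2.6, 2.3,   # COL4A2
     3.5,  2.8, 1.5,   # LAMB1
     3.4,  1.8, 1.7,   # ARID5B
     3.4,  1.7, 1.5,   # FSTL3
     3.2,  2.1, 1.5,   # TGFB1
     3.2,  1.9, 1.4,   # SMAD7
     2.8,  2.0, 1.7,   # CITED2
     2.8,  1.6, 0.9,   # GATA6
     2.6,  1.8, 1.5,   # SFRP5
     2.4,  1.7, 1.3,   # ID3
     2.4,  1.9, 1.3,   # LAMC3
     2.2,  1.7, 1.4,   # HAND2
     2.2,  1.3, 1.3,   # NDN
     2.1,  1.6, 1.4,   # PTN
     2.1,  1.4, 1.3,   # ZBTB20
     1.8,  1.5, 1.5,   # CDH1
     1.7,  1.3, 1.2,   # FGF7
     1.6,  1.4, 1.3,   # BMP2
     1.6,  1.2, 1.2,   # COL4A4
     1.5,  1.1, 1.0,   # CSNK1D
     1.4,  1.1, 1.1    # IRS2
  ), ncol = 3, byrow = TRUE)
  rownames(m) <- c("EPCAM", "MMP7", "KRT19", "MMP2", "VIM", "SOX9", "LAMA2",
                   "FGFR2", "KLF6", "COL4A2", "LAMB1", "ARID5B", "FSTL3",
                   "TGFB1", "SMAD7", "CITED2", "GATA6", "SFRP5", "ID3",
                   "LAMC3", "HAND2", "NDN", "PTN", "ZBTB20", "CDH1", "FGF7",
                   "BMP2", "COL4A4", "CSNK1D", "IRS2")
  colnames(m) <- c("CIR", "HCC_EARLY", "HCC_LATE")
  m
}

# Tumor-only genes with their printed fold-changes (early / late HCC).
.tumor_only_fc <- function() {
  m <- matrix(c(
    3.8, 1.8,  # DKK1
    2.4, 1.5,  # MMP1
    1.9, 2.1,  # FST
    1.3, 2.2,  # TBX3
    1.3, 1.3,  # MAP4K4
    1.3, 1.3,  # INHBA
    1.3, 1.3,  # HHEX
    1.3, 1.4,  # ATF2
    1.3, 1.4,  # BSG
    1.2, 1.3,  # LAMA4
    1.2, 1.1,  # FOXM1
    0.9, 0.7,  # KRAS
    0.7, 0.5,  # PROX1
    0.7, 0.6,  # TGFBR3
    0.6, 0.6,  # MST1
    0.6, 0.5   # STAT3
  ), ncol = 2, byrow = TRUE)
  rownames(m) <- c("DKK1", "MMP1", "FST", "TBX3", "MAP4K4", "INHBA", "HHEX",
                   "ATF2", "BSG", "LAMA4", "FOXM1", "KRAS", "PROX1",
                   "TGFBR3", "MST1", "STAT3")
  colnames(m) <- c("HCC_EARLY", "HCC_LATE")
  m
}

.down_persistent_genes <- function()
  c("FOXA1", "FOXA2", "GATA4", "HNF1A", "ACVR2B", "RXRA", "NRTN", "MMP15")

.late_only_genes <- function() c("ACVR1", "HMGA2", "IGF2", "CP", "YAP1")

.named_unchanged_genes <- function()
  c("BMP4", "HGF", "LHX2", "KDR", "ID1", "WNT2", "TNF", "NFKB1", "IL6",
    "CTNNB1", "CCND1", "SOX17", "KIT", "HLX", "FOXA3", "LEF1", "TCF3",
    "AFP", "ALB", "FGF2", "FGF4", "NF2")

.liver_stages <- function()
  c("specification", "migration", "bud_growth", "differentiation", "maturation")

#' Packaged gene-set registry
#'
#' Builds the default registry of curated gene sets: the 179-slot
#' liver-development set (stage-annotated), the 1,399-slot set of genes with
#' no expression evidence in normal liver, the 33 liver-gene/paralog pairs
#' (26 distinct paralogs), the ECM and BMP-pathway discrimination sets, and
#' the 4-gene BMP-inhibitor marker panel.  Slots beyond the genes actually
#' named in the source tables are synthetic placeholders (ids prefixed
#' \code{LIVDEV_}, \code{PARA_}, \code{SILENT_}).
#'
#' @return A list of class \code{gene_registry} with elements
#'   \code{liver_dev} (data frame: gene_id, stage, pattern),
#'   \code{silent} (character), \code{paralog_pairs} (data frame:
#'   liver_gene, paralog_gene, divergent), \code{ecm}, \code{bmp},
#'   \code{panel} (character vectors).
#' @export
default_registry <- function() {
  cirpk <- rownames(.cir_peak_fc())
  tonly <- rownames(.tumor_only_fc())
  downp <- .down_persistent_genes()
  late  <- .late_only_genes()
  ampl  <- c("GPC3", "GREM1", paste0("LIVDEV_A", sprintf("%02d", 1:8)))
  shsim <- c("BMPR1A", "TIMP2", "JUN", paste0("LIVDEV_S", sprintf("%02d", 1:26)))
  named_null <- .named_unchanged_genes()
  n_fill <- 179 - length(c(cirpk, tonly, downp, late, ampl, shsim, named_null)) - 2
  null_fill <- paste0("LIVDEV_N", sprintf("%02d", seq_len(n_fill) + 2))
  # LIVDEV_N01/N02 are background-level liver slots used as the two
  # non-divergent paralog pairs.
  low_null <- c("LIVDEV_N01", "LIVDEV_N02")
  unchanged <- c(named_null, low_null, null_fill)

  liver <- data.frame(
    gene_id = c(cirpk, tonly, downp, late, ampl, shsim, unchanged),
    pattern = c(rep("CIR_PEAK", length(cirpk)),
                rep("TUMOR_ONLY", length(tonly)),
                rep("DOWN_PERSISTENT", length(downp)),
                rep("LATE_ONLY", length(late)),
                rep("SHARED_AMPLIFIED", length(ampl)),
                rep("SHARED_SIMILAR", length(shsim)),
                rep("UNCHANGED", length(unchanged))),
    stringsAsFactors = FALSE)
  stopifnot(nrow(liver) == 179L, !anyDuplicated(liver$gene_id))
  liver$stage <- rep_len(.liver_stages(), nrow(liver))

  named_para <- c("BMP3", "CDH3", "FGF3", "FGF12", "GATA1", "RXRG", "SOX1")
  syn_para <- paste0("PARA_", sprintf("%02d", 8:26))
  paralogs <- c(named_para, syn_para)
  silent <- c(paralogs, paste0("SILENT_", sprintf("%04d", seq_len(1399 - 26))))

  named_pairs <- data.frame(
    liver_gene   = c("SOX9", "RXRA", "CDH1", "FGF7", "FGFR2", "GATA4",
                     "GATA6", "BMP2"),
    paralog_gene = c("SOX1", "RXRG", "CDH3", "FGF3", "FGF12", "GATA1",
                     "GATA1", "BMP3"),
    stringsAsFactors = FALSE)
  # 25 synthetic pairs: the 19 synthetic paralogs each pair with one
  # expressed liver gene; six paralogs pair with a second liver gene.
  expressed_partners <- c("EPCAM", "MMP7", "KRT19", "MMP2", "VIM", "LAMA2",
                          "KLF6", "COL4A2", "LAMB1", "ARID5B", "TGFB1",
                          "SMAD7", "CITED2", "SFRP5", "ID3", "LAMC3",
                          "HAND2", "DKK1", "MMP1", "TBX3", "HHEX", "PROX1",
                          "FOXA1")
  syn_pairs <- data.frame(
    liver_gene   = c(expressed_partners, "LIVDEV_N01", "LIVDEV_N02"),
    paralog_gene = c(rep_len(syn_para, length(expressed_partners)),
                     "PARA_25", "PARA_26"),
    stringsAsFactors = FALSE)
  pairs <- rbind(named_pairs, syn_pairs)
  stopifnot(nrow(pairs) == 33L,
            length(unique(pairs$paralog_gene)) == 26L)
  pairs$divergent <- !(pairs$liver_gene %in% low_null)

  reg <- list(
    liver_dev = liver,
    silent = silent,
    paralog_pairs = pairs,
    ecm = c("EPCAM", "MMP7", "MMP2", "LAMA2", "COL4A2", "LAMB1", "LAMC3",
            "HAND2", "CDH1", "COL4A4", "MMP1", "BSG", "LAMA4", "KRT19",
            "VIM"),
    bmp = c("BMP2", "BMPR1A", "ID3", "FGF7", "FGFR2", "SMAD7", "INHBA",
            "GPC3", "GREM1", "FSTL3", "FST"),
    panel = c("GPC3", "GREM1", "FSTL3", "FST"))
  class(reg) <- "gene_registry"
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$liver_dev$gene_id)) stopf("duplicate liver_dev gene ids")
  if (anyDuplicated(reg$silent)) stopf("duplicate silent gene ids")
  bad <- setdiff(reg$liver_dev$stage, .liver_stages())
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (!all(reg$paralog_pairs$paralog_gene %in% reg$silent))
    stopf("every paralog must be in the silent registry")
  if (any(reg$paralog_pairs$liver_gene == reg$paralog_pairs$paralog_gene))
    stopf("paralog pairs must reference distinct genes")
  invisible(reg)
}

#' @export
print.gene_registry <- function(x, ...) {
  cat(sprintf(paste0("gene_registry: %d liver-development genes, %d silent",
                     " genes, %d paralog pairs\n"),
              nrow(x$liver_dev), length(x$silent), nrow(x$paralog_pairs)))
  cat(sprintf("  ecm: %d  bmp: %d  panel: %s\n", length(x$ecm),
              length(x$bmp), paste(x$panel, collapse = ", ")))
  invisible(x)
}

#' Write a gene-set registry to YAML
#'
#' @param reg A \code{gene_registry}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(reg, path) {
  obj <- list(
    liver_dev = lapply(seq_len(nrow(reg$liver_dev)), function(i)
      as.list(reg$liver_dev[i, c("gene_id", "stage", "pattern")])),
    silent = as.list(reg$silent),
    paralog_pairs = lapply(seq_len(nrow(reg$paralog_pairs)), function(i)
      as.list(reg$paralog_pairs[i, ])),
    ecm = as.list(reg$ecm), bmp = as.list(reg$bmp), panel = as.list(reg$panel))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a gene-set registry from YAML
#'
#' @param path Path to a YAML file written by \code{\link{write_registry}}
#'   (or hand-edited in the same layout).
#' @return A \code{gene_registry}.
#' @export
read_registry <- function(path) {
  obj <- yaml::read_yaml(path)
  reg <- list(
    liver_dev = do.call(rbind, lapply(obj$liver_dev, function(e)
      data.frame(gene_id = e$gene_id, stage = e$stage, pattern = e$pattern,
                 stringsAsFactors = FALSE)))[, c("gene_id", "pattern", "stage")],
    silent = unlist(obj$silent),
    paralog_pairs = do.call(rbind, lapply(obj$paralog_pairs, function(e)
      data.frame(liver_gene = e$liver_gene, paralog_gene = e$paralog_gene,
                 divergent = isTRUE(e$divergent), stringsAsFactors = FALSE))),
    ecm = unlist(obj$ecm), bmp = unlist(obj$bmp), panel = unlist(obj$panel))
  class(reg) <- "gene_registry"
  validate_registry(reg)
  reg
}
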