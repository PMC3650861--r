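# Synthetic probe-level cohort generator.
#
# The generator emulates the statistical structure the downstream screens
# assume: log-normal baseline expression with additive effects on the log2
# scale, multiplicative per-group fold-changes, mean-preserving
# sub-population ("subset") effects that broaden or split tumor densities,
# transcriptionally silent genes pinned to the background-correction floor,
# per-probe affinity offsets, and per-array smooth technical bias in the
# probe covariates (GC fraction, melting temperature, position).

#' Build a cohort configuration
#'
#' @param genes Character vector of gene ids.
#' @param n_per_group Named integer vector of sample counts, names from
#'   \code{\link{sample_groups}()}. Default is the study cohort:
#'   12 NOR, 30 CIR, 31 early HCC, 18 late HCC.
#' @param group_effects Numeric matrix (genes x 4 groups, linear-scale
#'   fold-change vs baseline, all > 0), or NULL for no effects.
#' @param silent_flags Logical matrix (genes x 4 groups): TRUE entries are
#'   generated from the background floor distribution instead of the
#'   expression model. NULL for none.
#' @param subset_effects Data frame with columns \code{gene_id},
#'   \code{group}, \code{fraction} (in (0,1]) and \code{ratio} (> 1): a
#'   seeded random subset of that group's samples is shifted up and the
#'   rest down, preserving the group's planted mean fold-change while
#'   inflating its variance (skewed/bimodal tumor densities).
#' @param per_sample_log2 Optional numeric matrix (subset of genes x all
#'   samples, log2 additions) for planting per-sample structure such as the
#'   marker-panel coverage blocks.
#' @param baseline_log2 Optional named numeric vector of fixed per-gene
#'   baselines; genes not named draw from
#'   N(\code{baseline_log2_mean}, \code{baseline_log2_sd}).
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 level model.
#' @param probes_per_gene Probes per gene (>= 1).
#' @param noise_log2_sd Per-sample log2 measurement noise SD (>= 0).
#' @param bias_amplitudes Named vector \code{c(gc=, tm=, position=)} of
#'   log2 bias amplitudes for \code{\link{inject_technical_bias}}.
#' @param array_scale_log2_sd SD of per-array log2 scale offsets (>= 0).
#' @param bg_log2_mean,bg_log2_sd,bg_floor_linear,epsilon Background floor
#'   model for silent genes: linear value =
#'   max(epsilon, 2^N(bg_log2_mean, bg_log2_sd) - bg_floor_linear), i.e.
#'   most silent-gene values sit at the clamp with a small upper tail of
#'   non-specific signal.
#' @param master_seed Integer master seed; every stage derives its own
#'   stream from it, so identical seeds give bit-identical cohorts.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(genes,
                          n_per_group = c(NOR = 12, CIR = 30,
                                          HCC_EARLY = 31, HCC_LATE = 18),
                          group_effects = NULL,
                          silent_flags = NULL,
                          subset_effects = NULL,
                          per_sample_log2 = NULL,
                          baseline_log2 = NULL,
                          baseline_log2_mean = 9,
                          baseline_log2_sd = 1,
                          probes_per_gene = 4,
                          noise_log2_sd = 0.25,
                          bias_amplitudes = c(gc = 0, tm = 0, position = 0),
                          array_scale_log2_sd = 0,
                          bg_log2_mean = 6,
                          bg_log2_sd = 0.3,
                          bg_floor_linear = 82,
                          epsilon = 1,
                          master_seed = 1) {
  genes <- as.character(genes)
  if (!length(genes) || anyDuplicated(genes))
    stopf("configuration error: 'genes' must be non-empty and unique")
  if (!all(sample_groups() %in% names(n_per_group)))
    stopf("configuration error: 'n_per_group' must name all of %s",
          paste(sample_groups(), collapse = ", "))
  n_per_group <- n_per_group[sample_groups()]
  if (any(n_per_group < 1) || any(n_per_group != round(n_per_group)))
    stopf("configuration error: 'n_per_group' counts must be positive integers")
  if (is.null(group_effects)) {
    group_effects <- matrix(1, length(genes), 4,
                            dimnames = list(genes, sample_groups()))
  }
  if (!all(rownames(group_effects) == genes) ||
      !all(colnames(group_effects) == sample_groups()))
    stopf("configuration error: 'group_effects' must be genes x sample_groups()")
  if (any(group_effects <= 0))
    stopf("configuration error: 'group_effects' fold-changes must be > 0")
  if (is.null(silent_flags)) {
    silent_flags <- matrix(FALSE, length(genes), 4,
                           dimnames = list(genes, sample_groups()))
  }
  if (!is.null(subset_effects) && nrow(subset_effects)) {
    need <- c("gene_id", "group", "fraction", "ratio")
    if (!all(need %in% names(subset_effects)))
      stopf("configuration error: 'subset_effects' needs columns %s",
            paste(need, collapse = ", "))
    if (any(subset_effects$fraction <= 0 | subset_effects$fraction > 1))
      stopf("configuration error: 'subset_effects$fraction' must lie in (0, 1]")
    if (any(subset_effects$ratio <= 0))
      stopf("configuration error: 'subset_effects$ratio' must be > 0")
    if (!all(subset_effects$gene_id %in% genes))
      stopf("configuration error: 'subset_effects' references unknown genes")
  }
  assert_scalar_number(probes_per_gene, "probes_per_gene", lower = 1)
  assert_scalar_number(noise_log2_sd, "noise_log2_sd", lower = 0)
  assert_scalar_number(array_scale_log2_sd, "array_scale_log2_sd", lower = 0)
  assert_scalar_number(baseline_log2_sd, "baseline_log2_sd", lower = 0)
  if (!all(c("gc", "tm", "position") %in% names(bias_amplitudes)))
    stopf("configuration error: 'bias_amplitudes' must name gc, tm, position")

  structure(list(
    genes = genes, n_per_group = n_per_group,
    group_effects = group_effects, silent_flags = silent_flags,
    subset_effects = subset_effects, per_sample_log2 = per_sample_log2,
    baseline_log2 = baseline_log2,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    probes_per_gene = as.integer(probes_per_gene),
    noise_log2_sd = noise_log2_sd,
    bias_amplitudes = bias_amplitudes[c("gc", "tm", "position")],
    array_scale_log2_sd = array_scale_log2_sd,
    bg_log2_mean = bg_log2_mean, bg_log2_sd = bg_log2_sd,
    bg_floor_linear = bg_floor_linear, epsilon = epsilon,
    master_seed = as.integer(master_seed)), class = "cohort_config")
}

make_sample_table <- function(n_per_group) {
  prefix <- c(NOR = "NOR", CIR = "CIR", HCC_EARLY = "HCCE", HCC_LATE = "HCCL")
  do.call(rbind, lapply(sample_groups(), function(g) {
    n <- n_per_group[[g]]
    data.frame(sample_id = sprintf("%s_%02d", prefix[[g]], seq_len(n)),
               group = g, stringsAsFactors = FALSE)
  }))
}

# Draw from the silent-gene background floor model (linear scale).
rbackground <- function(n, config) {
  pmax(config$epsilon,
       2^stats::rnorm(n, config$bg_log2_mean, config$bg_log2_sd) -
         config$bg_floor_linear)
}

#' Generate a synthetic cohort
#'
#' Produces the probe-level table, the gene-level expression set and a
#' ground-truth record of every planted parameter.  Identical
#' \code{master_seed} reproduces bit-identical output.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return List with elements \code{probes} (\code{probe_table}, unbiased;
#'   pass through \code{\link{inject_technical_bias}} to add the planted
#'   technical bias), \code{expr} (\code{expr_set}, linear scale) and
#'   \code{truth} (\code{cohort_truth}).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stopf("'config' must be a cohort_config")
  genes <- config$genes
  samples <- make_sample_table(config$n_per_group)
  n_g <- length(genes); n_s <- nrow(samples)
  grp <- samples$group

  baseline <- with_stream(config$master_seed, "baseline", {
    b <- stats::rnorm(n_g, config$baseline_log2_mean, config$baseline_log2_sd)
    names(b) <- genes
    if (!is.null(config$baseline_log2)) {
      fixed <- intersect(names(config$baseline_log2), genes)
      b[fixed] <- config$baseline_log2[fixed]
    }
    b
  })

  # log2 signal: baseline + log2 group fold-change
  lfc <- log2(config$group_effects[, grp, drop = FALSE])
  signal <- matrix(baseline, n_g, n_s) + lfc
  dimnames(signal) <- list(genes, samples$sample_id)

  # mean-preserving subset effects: affected samples get ratio-fold more
  # than unaffected ones; the linear group mean stays at the planted
  # fold-change.
  subset_truth <- NULL
  if (!is.null(config$subset_effects) && nrow(config$subset_effects)) {
    se <- config$subset_effects
    subset_truth <- vector("list", nrow(se))
    with_stream(config$master_seed, "subset", {
      for (i in seq_len(nrow(se))) {
        g <- se$gene_id[i]; gset <- se$group[i]
        f <- se$fraction[i]; r <- se$ratio[i]
        idx <- which(grp == gset)
        k <- max(1L, round(f * length(idx)))
        aff <- sort(sample(idx, k))
        e0 <- 1 / (f * r + 1 - f)   # multiplies the planted mean fc
        adj <- rep(log2(e0), length(idx))
        adj[match(aff, idx)] <- log2(e0 * r)
        signal[g, idx] <- signal[g, idx] + adj
        subset_truth[[i]] <- data.frame(
          gene_id = g, group = gset, fraction = f, ratio = r,
          affected = paste(samples$sample_id[aff], collapse = ","),
          stringsAsFactors = FALSE)
      }
    })
    subset_truth <- do.call(rbind, subset_truth)
  }

  if (!is.null(config$per_sample_log2)) {
    ps <- config$per_sample_log2
    if (!all(rownames(ps) %in% genes) ||
        !all(colnames(ps) %in% samples$sample_id))
      stopf("configuration error: 'per_sample_log2' names unknown genes/samples")
    signal[rownames(ps), colnames(ps)] <-
      signal[rownames(ps), colnames(ps)] + ps
  }

  noise <- with_stream(config$master_seed, "noise",
    matrix(stats::rnorm(n_g * n_s, 0, config$noise_log2_sd), n_g, n_s))

  expr_lin <- 2^(signal + noise)

  # silent gene-groups: background floor only
  silent <- config$silent_flags[, grp, drop = FALSE]
  if (any(silent)) {
    idx <- which(silent)
    expr_lin[idx] <- with_stream(config$master_seed, "background",
                                 rbackground(length(idx), config))
  }
  dimnames(expr_lin) <- list(genes, samples$sample_id)
  expr <- expr_set(expr_lin, grp)

  # probe level: gene log2 value + per-probe affinity offset
  # (median-centred within gene so the gene value is the exact
  # median-polish limit)
  p <- config$probes_per_gene
  probe_gene <- rep(genes, each = p)
  probe_id <- sprintf("%s_p%d", probe_gene, rep(seq_len(p), times = n_g))
  affinity <- with_stream(config$master_seed, "affinity", {
    a <- stats::rnorm(n_g * p, 0, 0.25)
    a <- a - rep(vapply(split(a, rep(seq_len(n_g), each = p)),
                        stats::median, 0), each = p)
    a
  })
  covs <- with_stream(config$master_seed, "covariates", {
    gc <- stats::runif(n_g * p, 0.3, 0.8)
    data.frame(probe_id = probe_id, gene_id = probe_gene,
               gc_fraction = gc,
               melting_temp = 50 + 40 * (gc - 0.3) / 0.5 +
                 stats::rnorm(n_g * p, 0, 2),
               position_index = sample(0:599, n_g * p, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  probe_lin <- 2^(log2(expr_lin)[probe_gene, , drop = FALSE] + affinity)
  rownames(probe_lin) <- probe_id
  probes <- probe_table(covs, probe_lin, grp)

  # planted array bias parameters (applied by inject_technical_bias):
  # per-array coefficients alternate sign across arrays so the pooled
  # median reference is bias-free and reference-relative normalization can
  # recover the clean signal.
  bias <- with_stream(config$master_seed, "bias", {
    s <- rep_len(c(1, -1), n_s)
    data.frame(
      sample_id = samples$sample_id,
      scale_log2 = stats::rnorm(n_s, 0, config$array_scale_log2_sd),
      coef_gc = config$bias_amplitudes[["gc"]] * s * stats::runif(n_s, 0.9, 1.3),
      coef_tm = config$bias_amplitudes[["tm"]] * s * stats::runif(n_s, 0.9, 1.3),
      coef_position = config$bias_amplitudes[["position"]] * s *
        stats::runif(n_s, 0.9, 1.3),
      stringsAsFactors = FALSE)
  })

  truth <- structure(list(
    master_seed = config$master_seed,
    samples = cbind(samples, bias[, -1, drop = FALSE]),
    genes = data.frame(gene_id = genes, baseline_log2 = unname(baseline),
                       config$group_effects,
                       silent = config$silent_flags,
                       stringsAsFactors = FALSE, check.names = FALSE),
    subset_effects = subset_truth,
    per_sample_log2 = config$per_sample_log2,
    background = list(bg_log2_mean = config$bg_log2_mean,
                      bg_log2_sd = config$bg_log2_sd,
                      bg_floor_linear = config$bg_floor_linear,
                      epsilon = config$epsilon),
    bias_amplitudes = config$bias_amplitudes,
    probes_per_gene = config$probes_per_gene,
    noise_log2_sd = config$noise_log2_sd), class = "cohort_truth")

  list(probes = probes, expr = expr, truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("cohort_truth: %d genes, %d samples, master_seed %d\n",
              nrow(x$genes), nrow(x$samples), x$master_seed))
  invisible(x)
}

# Monotone bias basis: covariate scaled to [-1, 1] over its observed range.
bias_basis <- function(z) {
  rng <- range(z)
  if (diff(rng) == 0) return(rep(0, length(z)))
  2 * (z - rng[1]) / diff(rng) - 1
}

#' Add planted technical bias to a probe table
#'
#' Applies, on the log2 scale, each array's planted smooth monotone bias in
#' GC fraction, melting temperature and position, plus its scale offset,
#' as recorded in the cohort truth.  With all amplitudes zero the table is
#' returned unchanged.
#'
#' @param probes A \code{probe_table} from \code{\link{generate_cohort}}.
#' @param truth The matching \code{cohort_truth}.
#' @return A biased \code{probe_table}.
#' @export
inject_technical_bias <- function(probes, truth) {
  need <- c("gc_fraction", "melting_temp", "position_index")
  miss <- setdiff(need, names(probes$info))
  if (length(miss))
    stopf("probe table is missing covariate column(s): %s",
          paste(miss, collapse = ", "))
  st <- truth$samples
  if (!all(colnames(probes$intensities) %in% st$sample_id))
    stopf("truth does not cover all arrays in the probe table")
  st <- st[match(colnames(probes$intensities), st$sample_id), ]
  b_gc <- bias_basis(probes$info$gc_fraction)
  b_tm <- bias_basis(probes$info$melting_temp)
  b_pos <- bias_basis(probes$info$position_index)
  bias <- outer(b_gc, st$coef_gc) + outer(b_tm, st$coef_tm) +
    outer(b_pos, st$coef_position) +
    matrix(st$scale_log2, nrow(probes$intensities), nrow(st), byrow = TRUE)
  out <- probes
  out$intensities <- 2^(log2(probes$intensities) + bias)
  out
}

#' Paper-mimic cohort configuration
#'
#' The packaged study-condition configuration: 12 NOR / 30 CIR / 31 early /
#' 18 late samples over the full registry (179 liver-development slots plus
#' 1,399 silent slots).  Planted effects follow the printed fold-change
#' tables and body-text pattern counts: 98 liver genes carry effects in at
#' least one disease group; tumor effects of those genes are mean-preserving
#' subset effects (half the tumors shifted up, half down, 6-fold apart)
#' reproducing the broad, skewed tumor densities; silent genes (and the two
#' background-level liver slots used as non-divergent paralog pairs) sit at
#' the background floor in every group; the four BMP-inhibitor panel genes
#' carry per-sample coverage blocks so that every tumor sample exceeds a
#' 1.5 fold-change for exactly one designated panel gene.
#'
#' @param master_seed Master seed (default 17, the packaged cohort).
#' @param registry Gene-set registry (default \code{\link{default_registry}()}).
#' @return A \code{cohort_config}.
#' @export
study_mimic_config <- function(master_seed = 17, registry = default_registry()) {
  liver <- registry$liver_dev
  genes <- c(liver$gene_id, registry$silent)
  cp <- .cir_peak_fc(); to <- .tumor_only_fc()

  fc <- matrix(1, length(genes), 4, dimnames = list(genes, sample_groups()))
  fc[rownames(cp), c("CIR", "HCC_EARLY", "HCC_LATE")] <- cp
  fc[rownames(to), c("HCC_EARLY", "HCC_LATE")] <- to
  fc[.down_persistent_genes(), c("CIR", "HCC_EARLY", "HCC_LATE")] <-
    matrix(c(0.5, 0.55, 0.55), length(.down_persistent_genes()), 3, byrow = TRUE)
  fc[.late_only_genes(), "HCC_LATE"] <- 2.0
  ampl <- liver$gene_id[liver$pattern == "SHARED_AMPLIFIED"]
  fc[ampl, c("CIR", "HCC_EARLY", "HCC_LATE")] <-
    matrix(c(1.8, 4.0, 4.0), length(ampl), 3, byrow = TRUE)
  fc["GPC3", ] <- c(1, 2.0, 1, 1)     # tumor structure set per sample below
  fc["GREM1", ] <- c(1, 1.6, 1, 1)
  shs <- liver$gene_id[liver$pattern == "SHARED_SIMILAR"]
  fc[shs, c("CIR", "HCC_EARLY", "HCC_LATE")] <-
    matrix(c(2.0, 2.0, 2.0), length(shs), 3, byrow = TRUE)
  fc["BMPR1A", c("CIR", "HCC_EARLY", "HCC_LATE")] <- c(1.8, 1.6, 1.5)
  # panel genes: tumor-group means are carried by the per-sample blocks
  panel <- registry$panel
  fc[panel, c("HCC_EARLY", "HCC_LATE")] <- 1
  fc["FSTL3", "CIR"] <- 3.4
  fc["FST", "CIR"] <- 1.0

  silent_flags <- matrix(FALSE, length(genes), 4,
                         dimnames = list(genes, sample_groups()))
  silent_flags[registry$silent, ] <- TRUE
  low_liver <- liver$gene_id[liver$gene_id %in%
                               c("LIVDEV_N01", "LIVDEV_N02")]
  silent_flags[low_liver, ] <- TRUE

  # tumor subset effects for every DE liver gene except the panel genes
  # (per-sample blocks) and the down-persistent genes (which must stay as
  # tightly regulated in tumors as in cirrhosis)
  de <- liver$gene_id[liver$pattern != "UNCHANGED"]
  spread_genes <- setdiff(de, c(panel, .down_persistent_genes(),
                                .late_only_genes()))
  subset_effects <- rbind(
    data.frame(gene_id = rep(spread_genes, each = 2),
               group = rep(c("HCC_EARLY", "HCC_LATE"), length(spread_genes)),
               fraction = 0.5, ratio = 6, stringsAsFactors = FALSE),
    data.frame(gene_id = .late_only_genes(), group = "HCC_LATE",
               fraction = 0.5, ratio = 6, stringsAsFactors = FALSE))

  # marker-panel coverage blocks: tumor sample j is designated to panel
  # gene (j mod 4); the designated gene is planted 4x up, the others 0.8x.
  samples <- make_sample_table(c(NOR = 12, CIR = 30, HCC_EARLY = 31,
                                 HCC_LATE = 18))
  tumor <- samples$sample_id[samples$group %in% c("HCC_EARLY", "HCC_LATE")]
  ps <- matrix(0, length(panel), length(samples$sample_id),
               dimnames = list(panel, samples$sample_id))
  ps[, tumor] <- log2(0.8)
  for (j in seq_along(tumor))
    ps[((j - 1L) %% 4L) + 1L, tumor[j]] <- log2(4)

  cohort_config(
    genes = genes, group_effects = fc, silent_flags = silent_flags,
    subset_effects = subset_effects, per_sample_log2 = ps,
    bias_amplitudes = c(gc = 0.8, tm = 0.5, position = 0.4),
    array_scale_log2_sd = 0.2,
    master_seed = master_seed)
}

#' Write cohort truth to JSON
#'
#' @param truth A \code{cohort_truth}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- unclass(truth)
  if (!is.null(obj$per_sample_log2)) {
    obj$per_sample_log2 <- list(
      genes = rownames(truth$per_sample_log2),
      samples = colnames(truth$per_sample_log2),
      values = unname(as.data.frame(truth$per_sample_log2)))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read cohort truth from JSON
#'
#' @param path Path written by \code{\link{write_truth}}.
#' @return A \code{cohort_truth}.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$per_sample_log2)) {
    m <- as.matrix(as.data.frame(obj$per_sample_log2$values))
    dimnames(m) <- list(obj$per_sample_log2$genes, obj$per_sample_log2$samples)
    obj$per_sample_log2 <- m
  }
  for (nm in c("samples", "genes", "subset_effects"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.data.frame(obj[[nm]])
  structure(obj, class = "cohort_truth")
}
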