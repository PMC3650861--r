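# Probe-level preprocessing: background correction, covariate-regression
# normalization (the distribution-free replacement for quantile
# normalization), the classical quantile-normalization comparator, median
# polish summarization to gene level, and a generic array QC screen.

#' Background-correct a probe table
#'
#' Per array, subtracts the \code{floor_quantile} intensity quantile and
#' clamps the result at \code{epsilon}, so all values stay strictly
#' positive.
#'
#' @param probes A \code{probe_table} with raw positive intensities.
#' @param floor_quantile Quantile used as the background estimate, in
#'   [0, 0.5).
#' @param epsilon Positive clamp floor.
#' @return A background-corrected \code{probe_table}.
#' @export
background_correct <- function(probes, floor_quantile = 0.02, epsilon = 1.0) {
  if (floor_quantile < 0 || floor_quantile >= 0.5)
    stopf("'floor_quantile' must lie in [0, 0.5)")
  if (epsilon <= 0) stopf("'epsilon' must be > 0")
  # quantile type 1 (lower order statistic); a zero floor_quantile means
  # no background is subtracted
  bg <- if (floor_quantile == 0) rep(0, ncol(probes$intensities))
        else apply(probes$intensities, 2, stats::quantile,
                   probs = floor_quantile, names = FALSE, type = 1)
  m <- sweep(probes$intensities, 2, bg)
  m[m < epsilon] <- epsilon
  out <- probes
  out$intensities <- m
  out
}

# Running-median smoother of r against covariate z; window is a fraction of
# the probe count, by covariate rank.  Tied covariate values share the mean
# of their fitted values (probes with identical covariates must receive
# identical corrections).  The returned term is centred to mean zero.
runmed_term <- function(z, r, bandwidth_frac) {
  n <- length(r)
  if (length(unique(z)) < 2L) return(rep(0, n))
  k <- round(bandwidth_frac * n)
  k <- max(3L, min(k + (1L - k %% 2L), n - (1L - n %% 2L)))
  ord <- order(z)
  s <- r[ord]
  # the plain running median flattens a monotone trend inside half a
  # window of each end; the edge halves are replaced by a local linear
  # fit over one full window (which also lets the costly shrinking
  # end-rule be skipped)
  h <- (k - 1L) %/% 2L
  if (h >= 2L && n > k) {
    sm <- stats::runmed(s, k, endrule = "keep")
    i <- seq_len(k)
    f <- stats::lm.fit(cbind(1, i), s[i])$coefficients
    sm[seq_len(h)] <- f[1] + f[2] * seq_len(h)
    j <- seq(n - k + 1L, n)
    f <- stats::lm.fit(cbind(1, j), s[j])$coefficients
    sm[seq(n - h + 1L, n)] <- f[1] + f[2] * j[seq(k - h + 1L, k)]
  } else {
    sm <- stats::runmed(s, k, endrule = "median")
  }
  fit <- numeric(n)
  fit[ord] <- sm
  if (anyDuplicated(z)) fit <- stats::ave(fit, z)
  fit - mean(fit)
}

# Additive backfit of r on the three probe covariates.  GC fraction and
# melting temperature are strongly collinear on real arrays, which makes
# pure backfitting of near-linear trends converge at a rate of about the
# squared correlation per sweep; a least-squares initialization on the
# scaled covariates removes the shared linear component immediately, and
# the running-median sweeps then refine only the nonparametric remainder.
backfit_covariates <- function(covs, r, bandwidth_frac, n_backfit) {
  terms <- matrix(0, length(r), length(covs))
  basis <- vapply(covs, bias_basis, numeric(length(r)))
  usable <- apply(basis, 2, function(b) any(b != 0))
  if (any(usable)) {
    cf <- stats::lm.fit(cbind(1, basis[, usable, drop = FALSE]),
                        r)$coefficients[-1]
    cf[is.na(cf)] <- 0
    terms[, usable] <- sweep(basis[, usable, drop = FALSE], 2, cf, "*")
    terms <- sweep(terms, 2, colMeans(terms))
  }
  for (iter in seq_len(n_backfit)) {
    for (j in seq_along(covs)) {
      partial <- r - rowSums(terms[, -j, drop = FALSE])
      terms[, j] <- runmed_term(covs[[j]], partial, bandwidth_frac)
    }
  }
  terms
}

#' Covariate-regression normalization
#'
#' Normalizes each array against the pooled median pseudo-array by fitting,
#' on the log2 scale, an additive model of smooth bias terms in GC
#' fraction, melting temperature and probe position (distribution-free
#' running-median smoothers, backfitted), plus a robust per-array scale
#' offset.  The pooled reference's own covariate trend is estimated once
#' and removed from every array, so normalized arrays carry no residual
#' covariate dependence while all between-array (biological) structure is
#' preserved.
#'
#' @param probes A background-corrected \code{probe_table}.
#' @param bandwidth_frac Smoother window as a fraction of the probe count
#'   (by covariate rank).
#' @param n_backfit Backfitting sweeps over the three covariates.
#' @return List with \code{probes} (normalized \code{probe_table}) and
#'   \code{model} (a \code{normalization_model}: per-array tabulated bias
#'   terms and scale offsets, the reference definition, and the per-probe
#'   fitted values).
#' @export
covariate_normalize <- function(probes, bandwidth_frac = 0.3, n_backfit = 3) {
  if (nrow(probes$intensities) < 50)
    stopf("covariate normalization needs >= 50 probes")
  covs <- probes$info[c("gc_fraction", "melting_temp", "position_index")]
  constant <- vapply(covs, function(z) length(unique(z)) < 2L, NA)
  if (any(constant))
    warnf("constant covariate(s) %s: bias term fixed at 0",
          paste(names(covs)[constant], collapse = ", "))
  y <- log2(probes$intensities)
  ref <- apply(y, 1, stats::median)
  # The reference's own covariate trend is estimated on the gene-centred
  # reference (probe deviations from their gene's mean), so gene-to-gene
  # baseline variance does not leak estimation noise into the trend.
  ref_centred <- ref - stats::ave(ref, probes$info$gene_id)
  common <- rowSums(backfit_covariates(covs, ref_centred, bandwidth_frac,
                                       n_backfit))
  # centring a gene's P probes removes 1/P of the trend; rescale
  n_probes_gene <- stats::ave(ref, probes$info$gene_id, FUN = length)
  attenuation <- mean(1 - 1 / n_probes_gene)
  if (attenuation > 0) common <- common / attenuation

  n_arr <- ncol(y)
  fitted <- matrix(0, nrow(y), n_arr, dimnames = dimnames(y))
  offsets <- numeric(n_arr)
  for (a in seq_len(n_arr)) {
    d <- y[, a] - ref
    offsets[a] <- stats::median(d)
    terms <- backfit_covariates(covs, d - offsets[a], bandwidth_frac, n_backfit)
    fitted[, a] <- offsets[a] + rowSums(terms) + common
  }
  names(offsets) <- colnames(y)
  out <- probes
  out$intensities <- 2^(y - fitted)
  model <- structure(list(
    reference = ref, common_trend = common, offsets = offsets,
    fitted = fitted, bandwidth_frac = bandwidth_frac,
    n_backfit = n_backfit,
    covariates = as.data.frame(covs)), class = "normalization_model")
  list(probes = out, model = model)
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf(
    "normalization_model: %d probes x %d arrays (bandwidth %.2f, %d backfits)\n",
    length(x$reference), length(x$offsets), x$bandwidth_frac, x$n_backfit))
  invisible(x)
}

#' Quantile normalization (comparator)
#'
#' Classical quantile normalization: each array's sorted values are
#' replaced by the across-array mean of order statistics (ties share the
#' mean of their ranks' targets).  Provided as the comparator whose
#' fold-change compression under asymmetric differential expression
#' motivates the covariate regression.
#'
#' @param probes A \code{probe_table}.
#' @return A quantile-normalized \code{probe_table}.
#' @export
quantile_normalize <- function(probes) {
  if (ncol(probes$intensities) < 2) stopf("quantile normalization needs >= 2 arrays")
  out <- probes
  out$intensities <- limma::normalizeQuantiles(probes$intensities, ties = TRUE)
  dimnames(out$intensities) <- dimnames(probes$intensities)
  out
}

#' Summarize probes to gene level by median polish
#'
#' Tukey median polish of each gene's log2 probe-by-array submatrix; the
#' gene's value on each array is the overall effect plus the array effect,
#' back-transformed to the linear scale.  Single-probe genes pass through
#' unchanged.
#'
#' @param probes A \code{probe_table}.
#' @return An \code{expr_set} (gene x sample, linear scale); group labels
#'   are carried over from the probe table when present.
#' @export
summarize_probes <- function(probes) {
  y <- log2(probes$intensities)
  genes <- unique(probes$info$gene_id)
  rows <- split(seq_len(nrow(y)), probes$info$gene_id)[genes]
  out <- matrix(NA_real_, length(genes), ncol(y),
                dimnames = list(genes, colnames(y)))
  for (i in seq_along(genes)) {
    sub <- y[rows[[i]], , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[i, ] <- sub
    } else {
      # the iteration cap keeps the decomposition deterministic; the
      # occasional non-converged polish is still accurate to < 1e-3 log2
      mp <- suppressWarnings(
        stats::medpolish(sub, eps = 1e-6, maxiter = 10, trace.iter = FALSE))
      out[i, ] <- mp$overall + mp$col
    }
  }
  expr_set(2^out, probes$groups)
}

#' Flag outlier arrays
#'
#' Flags arrays whose log2 intensity distribution is far from the pooled
#' reference distribution (all arrays pooled), measured by the two-sample
#' Kolmogorov-Smirnov distance.
#'
#' @param probes A \code{probe_table} with at least 3 arrays.
#' @param cutoff K-S distance above which an array is flagged.
#' @return Character vector of flagged array ids (possibly empty).
#' @export
qc_flag_arrays <- function(probes, cutoff = 0.3) {
  y <- log2(probes$intensities)
  if (ncol(y) < 3) stopf("array QC needs >= 3 arrays")
  pooled <- as.vector(y)
  d <- vapply(seq_len(ncol(y)), function(a)
    ks_statistic(y[, a], pooled, alternative = "two_sided"), 0)
  colnames(y)[d > cutoff]
}
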