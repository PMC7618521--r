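#' Conversion-count container
#'
#' Holds total and labeled (T>C-converted) read counts per gene and sample
#' together with the sample metadata. Labeled counts carry the nascent
#' transcription signal of SLAM-seq-style assays.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param samples data frame with columns `sample_id`, `condition`,
#'   `timepoint_h`, `replicate`, one row per count column.
#' @param total_counts,labeled_counts integer matrices, genes x samples;
#'   `labeled_counts` may be `NULL` for plain (RNA-seq-type) matrices.
#' @return an object of class `conversion_counts`.
#' @export
conversion_counts <- function(gene_ids, samples, total_counts,
                              labeled_counts = NULL) {
  .assert(nrow(total_counts) == length(gene_ids),
          "total_counts rows must match gene_ids")
  .assert(ncol(total_counts) == nrow(samples),
          "sample metadata must cover every column")
  .assert(all(c("sample_id", "condition", "timepoint_h", "replicate") %in%
                names(samples)),
          "samples needs sample_id/condition/timepoint_h/replicate")
  if (any(total_counts < 0)) stop("negative total counts", call. = FALSE)
  if (!is.null(labeled_counts)) {
    .assert(all(dim(labeled_counts) == dim(total_counts)),
            "labeled_counts must match total_counts dimensions")
    if (any(labeled_counts < 0)) stop("negative labeled counts", call. = FALSE)
    bad <- which(labeled_counts > total_counts, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("labeled > total at gene %s, sample %s",
                   gene_ids[bad[1, 1]], samples$sample_id[bad[1, 2]]),
           call. = FALSE)
  }
  rownames(total_counts) <- gene_ids
  colnames(total_counts) <- samples$sample_id
  if (!is.null(labeled_counts)) {
    rownames(labeled_counts) <- gene_ids
    colnames(labeled_counts) <- samples$sample_id
  }
  structure(list(gene_ids = gene_ids, samples = samples,
                 total_counts = total_counts,
                 labeled_counts = labeled_counts),
            class = "conversion_counts")
}

#' @exportS3Method print conversion_counts
print.conversion_counts <- function(x, ...) {
  cat(sprintf("conversion_counts: %d genes x %d samples (%s labeled counts)\n",
              length(x$gene_ids), nrow(x$samples),
              if (is.null(x$labeled_counts)) "without" else "with"))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Computes one positive scaling factor per sample by the median-of-ratios
#' method: each sample's counts are divided by the per-gene geometric mean
#' across samples (over genes expressed in all samples) and the median ratio
#' is taken.
#'
#' @param counts nonnegative count matrix, genes x samples.
#' @return numeric vector of size factors, one per column.
#' @export
normalize_counts <- function(counts) {
  .assert(is.matrix(counts) && ncol(counts) >= 2, "need >= 2 samples")
  if (all(counts == 0)) stop("all-zero count matrix", call. = FALSE)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene with nonzero counts in all samples", call. = FALSE)
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logref)))
  unname(sf)
}

#' Estimate the new-RNA fraction from conversion counts
#'
#' Maximum-likelihood mixture weight of "new" reads given that a read is
#' labeled with probability `q_new = 1 - (1 - conversion_rate)^n_T_sites`
#' when new and `q_old = 1 - (1 - background_rate)^n_T_sites` when old.
#' Because the labeled count given the total is binomial in the mixture
#' probability, the interior MLE has the closed form
#' `(labeled/total - q_old) / (q_new - q_old)`, clamped to `[0, 1]` at the
#' boundary.
#'
#' @param total,labeled nonnegative integer vectors (per gene or aggregate).
#' @param conversion_rate,background_rate per-site conversion probabilities,
#'   `0 <= background_rate < conversion_rate < 1`.
#' @param n_T_sites number of convertible sites per read.
#' @return new-RNA fraction(s) in `[0, 1]`.
#' @export
estimate_new_fraction <- function(total, labeled, conversion_rate,
                                  background_rate = 0, n_T_sites = 20) {
  .assert(all(total >= 0) && all(labeled >= 0), "counts must be nonnegative")
  if (any(labeled > total)) stop("labeled > total", call. = FALSE)
  .assert(conversion_rate >= 0 && conversion_rate < 1 &&
            background_rate >= 0 && background_rate < 1,
          "rates must be in [0, 1)")
  q_new <- 1 - (1 - conversion_rate)^n_T_sites
  q_old <- 1 - (1 - background_rate)^n_T_sites
  if (abs(q_new - q_old) < 1e-12)
    stop("q_new equals q_old: new fraction is unidentifiable", call. = FALSE)
  p_hat <- ifelse(total > 0, labeled / total, NA_real_)
  pmin(1, pmax(0, (p_hat - q_old) / (q_new - q_old)))
}

# --- negative binomial differential test ------------------------------------

# Gene-wise method-of-moments dispersion pooled over the two groups.
# For k_j ~ NB(s_j * mu, alpha): Var(k_j/s_j) = mu/s_j + alpha*mu^2, so the
# within-group sample variance estimates mu*mean(1/s) + alpha*mu^2.
.mom_dispersion <- function(norm, sf, idx) {
  m <- rowMeans(norm[, idx, drop = FALSE])
  v <- .row_vars(norm[, idx, drop = FALSE])
  inv_s <- mean(1 / sf[idx])
  a <- (v - m * inv_s) / m^2
  a[!is.finite(a)] <- NA_real_
  a
}

#' Negative binomial Wald test between two sample groups
#'
#' Per-gene log2 fold change of normalized group means (with pseudocount)
#' and a Wald p-value using gene-wise method-of-moments NB dispersions
#' shrunk on the log scale toward a log-linear mean-dispersion trend.
#' Genes below the minimum mean normalized count are marked untested
#' (`p_value`/`fdr` = `NA`) and excluded from the Benjamini-Hochberg
#' adjustment.
#'
#' @param counts count matrix, genes x samples (for SLAM-type data pass the
#'   labeled counts; for RNA/nucRNA-type data the totals).
#' @param size_factors per-sample size factors covering `counts` columns, as
#'   from [normalize_counts()]; factors for unused columns are ignored.
#' @param groupA_samples,groupB_samples column names (or indices) of the two
#'   groups; the log2 fold change is B over A. At least 2 replicates each.
#' @param dispersion_mode `"shrunk"` (default), `"genewise"` or `"trend"`.
#' @param shrink_weight weight on the gene-wise log dispersion when
#'   `dispersion_mode = "shrunk"`.
#' @param min_count minimum mean normalized count for a gene to be tested.
#' @param pseudocount added to normalized group means before log2.
#' @return data frame with `gene_id`, `base_mean`, `lfc`, `p_value`, `fdr`,
#'   `tested`, `dispersion`.
#' @export
differential_test <- function(counts, size_factors,
                              groupA_samples, groupB_samples,
                              dispersion_mode = c("shrunk", "genewise",
                                                  "trend"),
                              shrink_weight = 0.5,
                              min_count = 5,
                              pseudocount = 0.5) {
  dispersion_mode <- match.arg(dispersion_mode)
  .assert(is.matrix(counts), "counts must be a matrix")
  idxA <- if (is.character(groupA_samples))
    match(groupA_samples, colnames(counts)) else as.integer(groupA_samples)
  idxB <- if (is.character(groupB_samples))
    match(groupB_samples, colnames(counts)) else as.integer(groupB_samples)
  if (anyNA(idxA) || anyNA(idxB))
    stop("group samples not found among count columns", call. = FALSE)
  if (length(idxA) < 2 || length(idxB) < 2)
    stop("each group needs >= 2 replicates", call. = FALSE)
  sf <- size_factors
  if (!is.null(names(sf))) sf <- sf[colnames(counts)]
  .assert(length(sf) == ncol(counts) && all(sf > 0),
          "size_factors must be positive, one per counts column")

  norm <- sweep(counts, 2, sf, "/")
  mA <- rowMeans(norm[, idxA, drop = FALSE])
  mB <- rowMeans(norm[, idxB, drop = FALSE])
  base_mean <- rowMeans(norm[, c(idxA, idxB), drop = FALSE])
  tested <- base_mean >= min_count
  lfc <- log2(mB + pseudocount) - log2(mA + pseudocount)

  nA <- length(idxA); nB <- length(idxB)
  aA <- .mom_dispersion(norm, sf, idxA)
  aB <- .mom_dispersion(norm, sf, idxB)
  a_raw <- ((nA - 1) * aA + (nB - 1) * aB) / (nA + nB - 2)
  a_raw[is.na(a_raw)] <- 0
  a_floor <- 1e-8

  # Mean-dispersion trend: arithmetic bin means of the raw moment
  # estimates (negative estimates included, keeping the bin means
  # unbiased), then a log-linear fit through the bins. Fitting the trend
  # through per-gene log dispersions would be biased low (Jensen) because
  # the few-replicate moment estimates are strongly right-skewed.
  fit_ok <- tested & base_mean > 0
  a_trend <- rep(max(mean(a_raw[tested], na.rm = TRUE), a_floor),
                 length(a_raw))
  if (sum(fit_ok) >= 50) {
    lx <- log(base_mean[fit_ok])
    bins <- cut(lx, breaks = 20)
    bm_y <- tapply(a_raw[fit_ok], bins, mean)
    bm_x <- tapply(lx, bins, mean)
    okb <- !is.na(bm_y) & bm_y > 0 & !is.na(bm_x)
    if (sum(okb) >= 3) {
      tr <- stats::lm(y ~ x, data = data.frame(x = bm_x[okb], y = log(bm_y[okb])))
      a_trend <- exp(stats::coef(tr)[1] +
                       stats::coef(tr)[2] * log(pmax(base_mean, 1e-8)))
    }
  }
  a_trend <- pmax(a_trend, a_floor)
  a_use <- switch(dispersion_mode,
                  genewise = pmax(a_raw, a_floor),
                  trend = a_trend,
                  shrunk = pmax(shrink_weight * pmax(a_raw, 0) +
                                  (1 - shrink_weight) * a_trend, a_floor))

  # Wald statistic on the log2 scale by the delta method:
  # Var(mean_g) = mu*mean(1/s)/n + alpha*mu^2/n per group
  varA <- mA * mean(1 / sf[idxA]) / nA + a_use * mA^2 / nA
  varB <- mB * mean(1 / sf[idxB]) / nB + a_use * mB^2 / nB
  se2 <- (varA / (mA + pseudocount)^2 + varB / (mB + pseudocount)^2) /
    log(2)^2
  z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  # Small-sample Wald: t reference with the pooled residual df plus the
  # prior df contributed by dispersion moderation (limma-style; the trend
  # is estimated from thousands of genes, so trend-only dispersions are
  # treated as known and referenced against the normal). The shrunk-mode
  # prior df was fixed once by null-simulation calibration.
  df_ref <- switch(dispersion_mode,
                   genewise = nA + nB - 2,
                   shrunk = nA + nB - 2 + 16 * (1 - shrink_weight) / 0.5,
                   trend = Inf)
  p <- 2 * stats::pt(-abs(z), df = df_ref)
  p[!tested] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(gene_id = rownames(counts) %||% as.character(seq_along(lfc)),
             base_mean = base_mean, lfc = lfc, p_value = p, fdr = fdr,
             tested = tested, dispersion = a_use,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential test on a conversion-count time course
#'
#' Convenience wrapper: selects the nascent (SLAM-type) or total
#' (RNA-type) signal, computes size factors on the totals, and contrasts a
#' treatment timepoint against the reference timepoint. For SLAM-type data
#' with known labeling rates the tested signal is the background-corrected
#' nascent count `(labeled - total * q_old) / (q_new - q_old)` (clamped at
#' 0), whose expected fold change equals the underlying nascent-rate fold
#' change; with unknown rates the raw labeled counts are tested (their fold
#' changes are attenuated toward 0 by background conversions).
#'
#' @param cc a [conversion_counts()] object; labeling rates are taken from
#'   its `labeling` field when present.
#' @param timepoint_h treated timepoint to contrast against the reference
#'   (the minimum timepoint in the metadata).
#' @param data_type `"slam"` tests nascent signal, `"rna"` total counts.
#' @param labeling optional list with `conversion_rate`, `background_rate`,
#'   `n_T_sites` overriding the object's labeling metadata.
#' @param ... passed to [differential_test()].
#' @return see [differential_test()].
#' @export
differential_timepoint <- function(cc, timepoint_h, data_type = c("slam",
                                                                  "rna"),
                                   labeling = NULL, ...) {
  data_type <- match.arg(data_type)
  .assert(inherits(cc, "conversion_counts"), "cc must be conversion_counts")
  mat <- if (data_type == "slam") {
    .assert(!is.null(cc$labeled_counts), "no labeled counts present")
    lb <- labeling %||% cc$labeling
    if (!is.null(lb)) {
      q_new <- 1 - (1 - lb$conversion_rate)^lb$n_T_sites
      q_old <- 1 - (1 - lb$background_rate)^lb$n_T_sites
      pmax((cc$labeled_counts - cc$total_counts * q_old) / (q_new - q_old),
           0)
    } else cc$labeled_counts
  } else cc$total_counts
  ref_tp <- min(cc$samples$timepoint_h)
  ref <- cc$samples$sample_id[cc$samples$timepoint_h == ref_tp]
  trt <- cc$samples$sample_id[cc$samples$timepoint_h == timepoint_h]
  if (length(trt) == 0)
    stop("timepoint not present in sample metadata", call. = FALSE)
  # Library depth always comes from the totals: global changes in the
  # labeled fraction are the nascent-transcription signal and must not be
  # absorbed into the size factors.
  sf <- normalize_counts(cc$total_counts)
  names(sf) <- colnames(mat)
  differential_test(mat, sf, ref, trt, ...)
}
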