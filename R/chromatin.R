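#' Annotate regions to their nearest TSS gene
#'
#' Assigns each region the gene whose transcription start site is nearest
#' to the region midpoint on the same chromosome, if within
#' `max_distance_bp`. Strand is ignored; ties are broken by the
#' lexicographically smaller gene id (deterministic). Coordinates are
#' 0-based half-open; the midpoint is `floor((start + end) / 2)`.
#'
#' @param regions data frame with `region_id`, `chrom`, `start`, `end`.
#' @param tss_table data frame with `gene_id`, `chrom`, `tss_position`
#'   (strand column optional and unused for distance).
#' @param max_distance_bp maximum midpoint-to-TSS distance (default 1 Mb,
#'   permissive enough to catch distal enhancers).
#' @return data frame `region_id`, `gene_id` (`NA` when unassigned),
#'   `distance_to_tss`.
#' @export
annotate_regions_to_genes <- function(regions, tss_table,
                                      max_distance_bp = 1e6) {
  .assert(all(c("region_id", "chrom", "start", "end") %in% names(regions)),
          "regions needs region_id/chrom/start/end")
  .assert(all(c("gene_id", "chrom", "tss_position") %in% names(tss_table)),
          "tss_table needs gene_id/chrom/tss_position")
  if (anyDuplicated(tss_table[c("gene_id", "tss_position")]))
    stop("tss_table must have unique (gene, tss) rows", call. = FALSE)
  if (any(regions$start >= regions$end))
    stop("malformed regions: start must be < end", call. = FALSE)
  mid <- floor((regions$start + regions$end) / 2)
  gene <- rep(NA_character_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  missing_chroms <- setdiff(unique(regions$chrom), unique(tss_table$chrom))
  if (length(missing_chroms) > 0)
    warning(sprintf("chromosome(s) absent from tss_table, left unassigned: %s",
                    paste(missing_chroms, collapse = ", ")))
  for (ch in intersect(unique(regions$chrom), unique(tss_table$chrom))) {
    ri <- which(regions$chrom == ch)
    tt <- tss_table[tss_table$chrom == ch, ]
    # sort TSS; among equal distances pick the lexicographically smaller gene
    ord <- order(tt$tss_position, tt$gene_id)
    tpos <- tt$tss_position[ord]
    tgene <- tt$gene_id[ord]
    for (i in ri) {
      d <- abs(tpos - mid[i])
      dmin <- min(d)
      if (dmin <= max_distance_bp) {
        cand <- tgene[d == dmin]
        gene[i] <- min(cand)
        dist[i] <- dmin
      }
    }
  }
  data.frame(region_id = regions$region_id, gene_id = gene,
             distance_to_tss = dist, stringsAsFactors = FALSE)
}

#' Per-sample depth scaling of region signals
#'
#' Divides each sample's (factor, condition, replicate) signal column by its
#' total over regions and multiplies by 1e6, yielding counts-per-million-like
#' units comparable across libraries.
#'
#' @param signal long data frame `region_id, factor, condition, replicate,
#'   signal`.
#' @return the data frame with `signal` rescaled.
#' @export
scale_signal_depth <- function(signal) {
  key <- interaction(signal$factor, signal$condition, signal$replicate,
                     drop = TRUE)
  tot <- stats::ave(signal$signal, key, FUN = sum)
  signal$signal <- signal$signal / tot * 1e6
  signal
}

#' Differential binding per region
#'
#' Mean replicate signal per condition (optionally after per-sample depth
#' scaling), then `log2((mean_B + pc) / (mean_A + pc))` per region.
#'
#' @param rs a `region_signal` object (or a list with `regions` and long
#'   `signal` as produced by [simulate_binding()] / [read_region_signal()]).
#' @param factor_name which factor's signal to contrast.
#' @param condA,condB control and treated condition labels; the log2 fold
#'   change is B over A.
#' @param pseudocount added to both means (default 1).
#' @param depth_scale per-sample depth scaling before averaging (default
#'   `TRUE`); set `FALSE` when signals are already library-scaled and
#'   global shifts must remain observable.
#' @return data frame `region_id, factor, log2fc, mean_A, mean_B` with one
#'   row per region of `rs`.
#' @export
differential_binding <- function(rs, factor_name, condA = "DMSO",
                                 condB = "BETi", pseudocount = 1,
                                 depth_scale = TRUE) {
  sig <- rs$signal[rs$signal$factor == factor_name, ]
  if (nrow(sig) == 0) stop("factor not present in signal", call. = FALSE)
  if (any(sig$signal < 0)) stop("negative signal", call. = FALSE)
  if (!all(c(condA, condB) %in% sig$condition))
    stop("missing condition for factor", call. = FALSE)
  if (depth_scale) sig <- scale_signal_depth(sig)
  region_ids <- rs$regions$region_id
  mean_cond <- function(cond) {
    s <- sig[sig$condition == cond, ]
    m <- tapply(s$signal, s$region_id, mean)
    as.numeric(m[region_ids])
  }
  mA <- mean_cond(condA)
  mB <- mean_cond(condB)
  data.frame(region_id = region_ids, factor = factor_name,
             log2fc = log2(mB + pseudocount) - log2(mA + pseudocount),
             mean_A = mA, mean_B = mB, stringsAsFactors = FALSE)
}

#' Reciprocal compensation score
#'
#' Formalizes reciprocal factor exchange at a region: the log2 change of
#' the gained factor minus the log2 change of the lost factor. Large
#' positive scores mark regions where the gained factor (e.g. p300) moves in
#' while the lost factor (e.g. BRD4) moves out.
#'
#' @param delta_lost,delta_gained data frames from [differential_binding()]
#'   over the same region universe.
#' @return data frame `region_id, score`.
#' @export
compensation_score <- function(delta_lost, delta_gained) {
  if (!setequal(delta_lost$region_id, delta_gained$region_id) ||
      nrow(delta_lost) != nrow(delta_gained))
    stop("deltas must share the same region universe", call. = FALSE)
  g <- delta_gained[match(delta_lost$region_id, delta_gained$region_id), ]
  data.frame(region_id = delta_lost$region_id,
             score = g$log2fc - delta_lost$log2fc,
             stringsAsFactors = FALSE)
}

#' Top fraction of regions by increased binding
#'
#' Returns the `ceiling(fraction * n)` regions with the largest log2 fold
#' change (ties broken by region id). Regions with non-positive log2fc are
#' never returned; if the cut would include any, the subset is truncated at
#' zero with a warning.
#'
#' @param deltas data frame from [differential_binding()].
#' @param fraction fraction of regions to keep, in (0, 1); default 0.05
#'   ("top 5%" of sites with increased binding).
#' @return character vector of region ids (possibly empty).
#' @export
top_fraction_sites <- function(deltas, fraction = 0.05) {
  if (nrow(deltas) == 0) stop("empty deltas", call. = FALSE)
  .assert(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  k <- ceiling(fraction * nrow(deltas))
  ord <- order(-deltas$log2fc, deltas$region_id)
  top <- deltas[ord[seq_len(k)], ]
  if (any(top$log2fc <= 0)) {
    warning("top fraction truncated at log2fc = 0")
    top <- top[top$log2fc > 0, ]
  }
  top$region_id
}

#' Cross-model concordance of top sites
#'
#' Tests whether regions in model A's top set are also shifted in model B:
#' the statistic is the mean log2fc in B over A's top sites minus the mean
#' over all other shared regions; significance by permutation of same-size
#' random subsets with add-one correction, one-sided for positive shifts.
#'
#' @param top_sites_A character vector of region ids (e.g. from
#'   [top_fraction_sites()] in model A).
#' @param deltas_B data frame from [differential_binding()] in model B.
#' @param n_perm number of permutations (>= 1000).
#' @param seed integer seed for the permutation draws.
#' @return list `shift_statistic`, `p_perm`, `n_top`, `n_regions`.
#' @export
cross_model_concordance <- function(top_sites_A, deltas_B, n_perm = 1000,
                                    seed = 1L) {
  .assert(n_perm >= 1000, "n_perm must be >= 1000")
  shared <- intersect(top_sites_A, deltas_B$region_id)
  if (length(shared) == 0) stop("no shared regions", call. = FALSE)
  x <- deltas_B$log2fc
  in_top <- deltas_B$region_id %in% shared
  obs <- mean(x[in_top]) - mean(x[!in_top])
  k <- sum(in_top); n <- length(x)
  set.seed(seed)
  tot <- sum(x)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, k)
    s <- sum(x[idx])
    s / k - (tot - s) / (n - k)
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  list(shift_statistic = obs, p_perm = p, n_top = k, n_regions = n)
}

#' Average signal profile over aligned windows (metagene curve)
#'
#' For each region, takes the window `[midpoint - flank, midpoint + flank)`
#' of per-position signal, mean-pools it into `n_bins` bins, and averages
#' the binned curves across regions. Windows falling outside the available
#' chromosome signal are skipped (count reported via attribute
#' `n_skipped`).
#'
#' @param position_signal named list, one numeric vector of per-position
#'   signal per chromosome (position 1 = chromosome coordinate 0).
#' @param regions data frame with `chrom`, `start`, `end`.
#' @param flank_bp half-window size in bp.
#' @param n_bins number of output bins (>= 10).
#' @return numeric vector of length `n_bins`; attribute `n_skipped` reports
#'   skipped regions.
#' @export
metagene_profile <- function(position_signal, regions, flank_bp = 1000,
                             n_bins = 50) {
  .assert(n_bins >= 10, "n_bins must be >= 10")
  L <- 2 * flank_bp
  bin_of <- floor((seq_len(L) - 1) * n_bins / L) + 1
  acc <- matrix(NA_real_, nrow(regions), n_bins)
  skipped <- 0
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    sig <- position_signal[[ch]]
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    lo <- mid - flank_bp + 1   # 1-based index of coordinate mid - flank
    hi <- mid + flank_bp
    if (is.null(sig) || lo < 1 || hi > length(sig)) {
      skipped <- skipped + 1
      next
    }
    w <- sig[lo:hi]
    acc[i, ] <- as.numeric(tapply(w, bin_of, mean))
  }
  used <- stats::complete.cases(acc)
  if (!any(used)) stop("no region window fits the signal", call. = FALSE)
  curve <- colMeans(acc[used, , drop = FALSE])
  attr(curve, "n_skipped") <- skipped
  curve
}
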