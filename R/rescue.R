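#' Thresholds for temporal rescue classification
#'
#' Operational reading of "significantly decreased early, recovered late":
#' a gene is *rescued* when it drops significantly at the early timepoint
#' and either returns above an absolute floor or rebounds by at least
#' `delta_min` log2 units by the late timepoint.
#'
#' @param alpha FDR level for significance calls.
#' @param t_down log2 magnitude a decrease must reach (positive).
#' @param t_recover log2 floor for "recovered": late lfc must be
#'   `>= -t_recover` (positive number).
#' @param delta_min minimum late-minus-early lfc rebound (alternative route
#'   to "recovered").
#' @return a `rescue_thresholds` list.
#' @export
rescue_thresholds <- function(alpha = 0.05, t_down = log2(1.5),
                              t_recover = log2(1.25), delta_min = 1.0) {
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  .assert(t_down > 0, "t_down must be > 0")
  .assert(delta_min >= 0, "delta_min must be >= 0")
  structure(list(alpha = alpha, t_down = t_down, t_recover = t_recover,
                 delta_min = delta_min), class = "rescue_thresholds")
}

#' Classify genes by temporal response to treatment
#'
#' Joins the early (4 h) and late (24 h) differential results on their
#' shared gene universe and assigns exactly one class per gene with
#' precedence rescued > redundant > induced > unchanged:
#' \describe{
#'   \item{rescued}{significant decrease early
#'     (`fdr4 <= alpha`, `lfc4 <= -t_down`) AND recovered late
#'     (`lfc24 >= -t_recover` OR `lfc24 - lfc4 >= delta_min`).}
#'   \item{redundant}{significant decrease at both timepoints with no
#'     rebound (not rescued).}
#'   \item{induced}{significant increase late
#'     (`fdr24 <= alpha`, `lfc24 >= t_down`).}
#'   \item{unchanged}{everything else (including genes significant only at
#'     24 h in the downward direction).}
#' }
#' Genes untested (NA fdr) at either timepoint are classed unchanged.
#'
#' @param diff4,diff24 data frames from [differential_test()] for the early
#'   and late contrasts (must share gene ids; the inner join is used and
#'   dropped genes are reported via attribute `n_dropped`).
#' @param th a [rescue_thresholds()].
#' @return data frame `gene_id, lfc4, fdr4, lfc24, fdr24, class`.
#' @export
classify_rescue <- function(diff4, diff24, th = rescue_thresholds()) {
  .assert(inherits(th, "rescue_thresholds"), "th must be rescue_thresholds")
  common <- intersect(diff4$gene_id, diff24$gene_id)
  if (length(common) == 0)
    stop("no genes shared between the two differential results",
         call. = FALSE)
  d4 <- diff4[match(common, diff4$gene_id), ]
  d24 <- diff24[match(common, diff24$gene_id), ]
  lfc4 <- d4$lfc; fdr4 <- d4$fdr
  lfc24 <- d24$lfc; fdr24 <- d24$fdr
  sig_down4 <- !is.na(fdr4) & fdr4 <= th$alpha & lfc4 <= -th$t_down
  sig_down24 <- !is.na(fdr24) & fdr24 <= th$alpha & lfc24 <= -th$t_down
  recovered <- lfc24 >= -th$t_recover | (lfc24 - lfc4) >= th$delta_min
  sig_up24 <- !is.na(fdr24) & fdr24 <= th$alpha & lfc24 >= th$t_down

  cls <- rep("unchanged", length(common))
  cls[sig_up24] <- "induced"
  cls[sig_down4 & sig_down24 & !recovered] <- "redundant"
  cls[sig_down4 & recovered] <- "rescued"
  out <- data.frame(gene_id = common, lfc4 = lfc4, fdr4 = fdr4,
                    lfc24 = lfc24, fdr24 = fdr24, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- length(diff4$gene_id) + length(diff24$gene_id) -
    2 * length(common)
  out
}

#' Correlate binding changes with transcription changes
#'
#' Spearman rank correlation between per-gene binding log2 deltas and
#' expression log2 deltas, matched by gene id.
#'
#' @param binding_delta,expr_delta named numeric vectors (names = gene ids)
#'   of log2 changes; only genes present in both are used.
#' @param min_genes minimum number of matched genes (default 10).
#' @return list `spearman_rho`, `p_value`, `n_matched`.
#' @export
correlate_binding_transcription <- function(binding_delta, expr_delta,
                                            min_genes = 10) {
  .assert(!is.null(names(binding_delta)) && !is.null(names(expr_delta)),
          "both vectors must be named by gene id")
  common <- intersect(names(binding_delta), names(expr_delta))
  if (length(common) < min_genes)
    stop(sprintf("only %d matched genes (need >= %d)", length(common),
                 min_genes), call. = FALSE)
  x <- binding_delta[common]
  y <- expr_delta[common]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(spearman_rho = unname(ct$estimate), p_value = ct$p.value,
       n_matched = length(common))
}
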