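#' Temporal archetype templates over the four resistance stages
#'
#' Canonical shapes over the ordered stages (untreated, short-term treated,
#' incipient resistance, full resistance):
#' \describe{
#'   \item{evolution}{monotone increase `(0, 1, 2, 3)`.}
#'   \item{degression}{monotone decrease `(3, 2, 1, 0)`.}
#'   \item{stress}{transient early bump `(0, 1, 0, 0)`.}
#'   \item{inflammation}{incipient-resistance-only bump `(0, 0, 1, 0)`.}
#'   \item{interferon}{up early and at incipient resistance, down at full
#'     resistance `(0, 1, 1, -1)`.}
#' }
#'
#' @param stage_labels column names for the four stages.
#' @return 5 x 4 numeric matrix, one template per row.
#' @export
archetype_templates <- function(stage_labels = c("DMSO", "BETi_72h",
                                                 "IC50_r", "IC90_r")) {
  t <- rbind(evolution    = c(0, 1, 2, 3),
             degression   = c(3, 2, 1, 0),
             stress       = c(0, 1, 0, 0),
             inflammation = c(0, 0, 1, 0),
             interferon   = c(0, 1, 1, -1))
  colnames(t) <- stage_labels
  t
}

#' Select the most variable genes
#'
#' The `n` genes with the largest variance of stage means after a
#' `log2(x + pseudocount)` transform; ties broken by gene id.
#'
#' @param profiles gene-by-stage matrix (rownames = gene ids).
#' @param n number of genes to keep (default 100, the usual heatmap size).
#' @param pseudocount added before log2 (default 1); set `NA` to skip the
#'   log transform.
#' @return character vector of `n` gene ids, in decreasing variance order.
#' @export
select_variable_genes <- function(profiles, n = 100, pseudocount = 1) {
  .assert(is.matrix(profiles), "profiles must be a matrix")
  if (n > nrow(profiles))
    stop("n exceeds the number of genes", call. = FALSE)
  x <- if (is.na(pseudocount)) profiles else log2(profiles + pseudocount)
  v <- .row_vars(x)
  ids <- rownames(profiles) %||% as.character(seq_len(nrow(profiles)))
  ord <- order(-v, ids)
  ids[ord[seq_len(n)]]
}

#' Hierarchical clustering of stage profiles
#'
#' Profiles are z-scored per gene across stages, clustered with Ward
#' linkage on Euclidean distances, and cut at `k` clusters. Constant
#' profiles (zero variance) cannot be z-scored; they are assigned the
#' cluster of their nearest non-constant neighbour (Euclidean on raw
#' profiles) and flagged via the `constant_genes` attribute.
#'
#' @param profiles gene-by-stage matrix.
#' @param k number of clusters (>= 2); 2 for a simple up/down split, 5 for
#'   the full archetype repertoire.
#' @return integer vector of cluster ids named by gene; attribute
#'   `constant_genes` lists flagged genes.
#' @export
hierarchical_cluster <- function(profiles, k) {
  .assert(is.matrix(profiles) && nrow(profiles) >= k, "need >= k genes")
  .assert(k >= 2, "k must be >= 2")
  ids <- rownames(profiles) %||% as.character(seq_len(nrow(profiles)))
  sds <- sqrt(.row_vars(profiles))
  const <- sds == 0
  z <- (profiles - rowMeans(profiles)) / ifelse(const, 1, sds)
  zv <- z[!const, , drop = FALSE]
  if (nrow(zv) < k)
    stop("fewer non-constant genes than clusters", call. = FALSE)
  hc <- stats::hclust(stats::dist(zv), method = "ward.D2")
  cl_var <- stats::cutree(hc, k = k)
  cl <- integer(nrow(profiles))
  names(cl) <- ids
  cl[!const] <- cl_var
  if (any(const)) {
    for (i in which(const)) {
      d <- sqrt(rowSums((profiles[!const, , drop = FALSE] -
                           matrix(profiles[i, ], sum(!const), ncol(profiles),
                                  byrow = TRUE))^2))
      cl[i] <- cl_var[which.min(d)]
    }
  }
  attr(cl, "constant_genes") <- ids[const]
  cl
}

#' Assign temporal archetypes by template correlation
#'
#' Each gene's stage profile is correlated (Pearson, on z-scored values —
#' equivalent to raw Pearson) with the five archetype templates; the gene is
#' assigned the best-correlated archetype, or `flat` when the best
#' correlation is below the floor or tied.
#'
#' @param profiles gene-by-stage matrix over exactly 4 ordered stages.
#' @param min_correlation correlation floor below which a gene is `flat`
#'   (default 0.5, avoiding forced labels on noise).
#' @return data frame `gene_id, archetype, template_correlation, cluster_id`
#'   (`cluster_id` is the archetype's index, 0 for flat).
#' @export
assign_archetypes <- function(profiles, min_correlation = 0.5) {
  .assert(is.matrix(profiles), "profiles must be a matrix")
  if (ncol(profiles) != 4)
    stop("exactly 4 ordered stages are required", call. = FALSE)
  templates <- archetype_templates(colnames(profiles) %||%
                                     c("DMSO", "BETi_72h", "IC50_r",
                                       "IC90_r"))
  ids <- rownames(profiles) %||% as.character(seq_len(nrow(profiles)))
  cors <- suppressWarnings(stats::cor(t(profiles), t(templates)))
  cors[!is.finite(cors)] <- -Inf  # constant profiles correlate with nothing
  best <- max.col(cors, ties.method = "first")
  best_r <- cors[cbind(seq_len(nrow(cors)), best)]
  # ties between distinct templates -> flat
  n_best <- rowSums(cors == best_r & is.finite(best_r))
  arch <- rownames(templates)[best]
  flat <- !is.finite(best_r) | best_r < min_correlation | n_best > 1
  arch[flat] <- "flat"
  data.frame(gene_id = ids, archetype = arch,
             template_correlation = ifelse(is.finite(best_r), best_r,
                                           NA_real_),
             cluster_id = ifelse(flat, 0L, best),
             stringsAsFactors = FALSE)
}

#' Per-archetype stage summaries with a paired co-inhibitor arm
#'
#' @param profiles control gene-by-stage matrix.
#' @param paired matched co-treated matrix (same genes and stages).
#' @param assignments data frame from [assign_archetypes()] (or any
#'   `gene_id`/`archetype` table covering the genes).
#' @return data frame `archetype, stage, mean, sd, mean_paired, sd_paired,
#'   log2_ratio` where `log2_ratio` contrasts the paired arm with control.
#' @export
stage_response_summary <- function(profiles, paired, assignments) {
  if (is.null(paired)) stop("paired arm is required", call. = FALSE)
  .assert(all(dim(profiles) == dim(paired)),
          "paired arm must match control dimensions")
  ids <- rownames(profiles) %||% as.character(seq_len(nrow(profiles)))
  arch <- assignments$archetype[match(ids, assignments$gene_id)]
  .assert(!anyNA(arch), "assignments must cover every gene")
  stages <- colnames(profiles) %||% as.character(seq_len(ncol(profiles)))
  out <- do.call(rbind, lapply(unique(arch), function(a) {
    rows <- arch == a
    do.call(rbind, lapply(seq_along(stages), function(s) {
      x <- profiles[rows, s]; y <- paired[rows, s]
      data.frame(archetype = a, stage = stages[s],
                 mean = mean(x), sd = stats::sd(x),
                 mean_paired = mean(y), sd_paired = stats::sd(y),
                 log2_ratio = log2(mean(y) / mean(x)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Gene-set fold-change contrasts (blunting statistic)
#'
#' Summarizes per-gene log2 fold changes within named gene sets and tests,
#' for every ordered set pair, whether set A is less down-regulated than
#' set B (one-sided Mann-Whitney, A stochastically greater), with
#' Benjamini-Hochberg correction across pairs. Sets with fewer than
#' `min_genes` matched genes are excluded with a warning.
#'
#' @param per_gene_lfc named numeric vector of log2 fold changes.
#' @param genesets named list of gene-id vectors.
#' @param min_genes minimum matched genes per set (default 5).
#' @return list with `set_summary` (`set, n, mean_lfc, sd_lfc`) and
#'   `pairwise` (`set_A, set_B, mean_diff, p_value, fdr`).
#' @export
geneset_delta <- function(per_gene_lfc, genesets, min_genes = 5) {
  .assert(!is.null(names(per_gene_lfc)), "per_gene_lfc must be named")
  matched <- lapply(genesets, function(g)
    per_gene_lfc[names(per_gene_lfc) %in% g])
  keep <- vapply(matched, length, integer(1)) >= min_genes
  if (any(!keep))
    warning(sprintf("excluding gene set(s) with < %d matched genes: %s",
                    min_genes, paste(names(genesets)[!keep],
                                     collapse = ", ")))
  matched <- matched[keep]
  if (length(matched) == 0) stop("no usable gene sets", call. = FALSE)
  set_summary <- data.frame(set = names(matched),
                            n = vapply(matched, length, integer(1)),
                            mean_lfc = vapply(matched, mean, numeric(1)),
                            sd_lfc = vapply(matched, stats::sd, numeric(1)),
                            stringsAsFactors = FALSE, row.names = NULL)
  pairs <- NULL
  if (length(matched) >= 2) {
    combos <- expand.grid(A = names(matched), B = names(matched),
                          stringsAsFactors = FALSE)
    combos <- combos[combos$A != combos$B, ]
    pairs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      a <- matched[[combos$A[i]]]; b <- matched[[combos$B[i]]]
      wt <- suppressWarnings(stats::wilcox.test(a, b,
                                                alternative = "greater",
                                                exact = FALSE))
      data.frame(set_A = combos$A[i], set_B = combos$B[i],
                 mean_diff = mean(a) - mean(b), p_value = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
    pairs$fdr <- stats::p.adjust(pairs$p_value, method = "BH")
    rownames(pairs) <- NULL
  }
  list(set_summary = set_summary, pairwise = pairs)
}
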