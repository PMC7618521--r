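#' Simulation configuration for the treatment time course
#'
#' Bundles every parameter of the synthetic SLAM-seq-style time course:
#' gene classes planted with known temporal log2 fold changes, negative
#' binomial count noise, and T>C-style conversion labeling. The defaults
#' describe the study conditions emulated throughout the package: 5000 genes,
#' 10% rescued (transcription drops 4-fold at 4 h and returns to baseline by
#' 24 h), three replicates per timepoint at 0/4/24 h, NB dispersion 0.1.
#'
#' @param n_genes number of genes to simulate.
#' @param class_proportions named fractions over the classes
#'   `rescued`, `redundant`, `induced`, `unchanged`; must sum to 1.
#' @param lfc4_rescued,lfc24_rescued planted log2 fold change (vs 0 h) of the
#'   nascent rate of rescued genes at 4 h (negative) and 24 h (near 0).
#' @param lfc_redundant planted log2 fold change of redundant genes at both
#'   4 h and 24 h (negative, no rebound).
#' @param lfc_induced planted 24 h log2 fold change of induced genes (their
#'   4 h change is 0).
#' @param dispersion negative binomial dispersion of total counts
#'   (`var = mu + dispersion * mu^2`); must be > 0.
#' @param n_reps replicates per timepoint (>= 2).
#' @param timepoints_h timepoints in hours; the first is the untreated
#'   reference.
#' @param mean_expression_log_mu,mean_expression_log_sigma meanlog/sdlog of
#'   the log-normal baseline expected total counts per gene.
#' @param baseline_new_fraction fraction of reads from new transcripts at the
#'   reference timepoint; planted fold changes scale this fraction.
#' @param conversion_rate per-site T>C conversion probability on reads from
#'   new transcripts.
#' @param background_rate per-site background conversion probability on reads
#'   from pre-existing transcripts; must be < `conversion_rate`.
#' @param n_T_sites number of convertible sites per read (fixed at 20 by
#'   default); a read is "labeled" when it carries at least one conversion.
#' @param deterministic_classes if `TRUE`, allocate exactly
#'   `floor(n_genes * proportion)` genes per class (remainder to the largest
#'   class) instead of multinomial sampling; useful for exact-count tests.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 5000,
                       class_proportions = c(rescued = 0.10, redundant = 0.15,
                                             induced = 0.05, unchanged = 0.70),
                       lfc4_rescued = -2, lfc24_rescued = 0,
                       lfc_redundant = -2,
                       lfc_induced = 1.5,
                       dispersion = 0.1,
                       n_reps = 3,
                       timepoints_h = c(0, 4, 24),
                       mean_expression_log_mu = 7.3,
                       mean_expression_log_sigma = 1,
                       baseline_new_fraction = 0.5,
                       conversion_rate = 0.05,
                       background_rate = 0.001,
                       n_T_sites = 20,
                       deterministic_classes = FALSE,
                       seed = 1L) {
  classes <- c("rescued", "redundant", "induced", "unchanged")
  .assert(is.numeric(n_genes) && n_genes >= 1, "n_genes must be >= 1")
  .assert(all(names(class_proportions) %in% classes) &&
            !anyDuplicated(names(class_proportions)),
          "class_proportions must be named with rescued/redundant/induced/unchanged")
  .assert(all(class_proportions >= 0),
          "class_proportions must be nonnegative")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1", call. = FALSE)
  .assert(dispersion > 0, "dispersion must be > 0")
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  .assert(length(timepoints_h) >= 2 && timepoints_h[1] == 0,
          "timepoints_h must start at 0 (reference)")
  .assert(background_rate >= 0 && background_rate < conversion_rate &&
            conversion_rate <= 1,
          "need 0 <= background_rate < conversion_rate <= 1")
  .assert(baseline_new_fraction > 0 && baseline_new_fraction <= 1,
          "baseline_new_fraction must be in (0, 1]")
  props <- stats::setNames(rep(0, length(classes)), classes)
  props[names(class_proportions)] <- class_proportions
  cfg <- list(n_genes = as.integer(n_genes),
              class_proportions = props,
              lfc4_rescued = lfc4_rescued, lfc24_rescued = lfc24_rescued,
              lfc_redundant = lfc_redundant, lfc_induced = lfc_induced,
              dispersion = dispersion, n_reps = as.integer(n_reps),
              timepoints_h = timepoints_h,
              mean_expression_log_mu = mean_expression_log_mu,
              mean_expression_log_sigma = mean_expression_log_sigma,
              baseline_new_fraction = baseline_new_fraction,
              conversion_rate = conversion_rate,
              background_rate = background_rate,
              n_T_sites = as.integer(n_T_sites),
              deterministic_classes = isTRUE(deterministic_classes),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.allocate_classes <- function(cfg) {
  p <- cfg$class_proportions
  n <- cfg$n_genes
  if (cfg$deterministic_classes) {
    counts <- floor(n * p)
    # remainder to classes with the largest fractional parts
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- n * p - counts
      top <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1
    }
    rep(names(p), counts)
  } else {
    sample(names(p), n, replace = TRUE, prob = p)
  }
}

# planted per-timepoint log2 fold changes of the nascent rate, by class
.class_lfcs <- function(cfg, class) {
  switch(class,
         rescued   = c(cfg$lfc4_rescued, cfg$lfc24_rescued),
         redundant = c(cfg$lfc_redundant, cfg$lfc_redundant),
         induced   = c(0, cfg$lfc_induced),
         unchanged = c(0, 0))
}

#' Simulate a labeled time-course count matrix with planted gene classes
#'
#' Generates total and labeled (converted) read counts per gene and sample
#' for a treatment time course. Total counts are negative binomial around a
#' gene-specific log-normal baseline and do not change with time (total RNA
#' pools turn over slowly); the planted temporal signal lives in the nascent
#' fraction: at each post-treatment timepoint the fraction of "new" reads is
#' the baseline fraction scaled by `2^lfc` for the gene's class. Each read is
#' labeled with probability `q_new = 1 - (1 - conversion_rate)^n_T_sites` if
#' new and `q_old = 1 - (1 - background_rate)^n_T_sites` otherwise, so the
#' labeled count given the total is binomial with the mixture probability.
#'
#' @param config a [sim_config()].
#' @return a list with components `counts` (a `conversion_counts` object:
#'   `gene_ids`, `samples` data frame, `total_counts` and `labeled_counts`
#'   matrices) and `truth` (a data frame with `gene_id`, `true_class`,
#'   `true_lfc4`, `true_lfc24`, `linked_region_id`).
#' @export
simulate_timecourse_counts <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("gene_%05d", seq_len(n))
  cls <- .allocate_classes(config)
  lfcs <- t(vapply(cls, .class_lfcs, numeric(2), cfg = config))
  truth <- data.frame(gene_id = gene_ids,
                      true_class = cls,
                      true_lfc4 = lfcs[, 1],
                      true_lfc24 = lfcs[, 2],
                      linked_region_id = sprintf("region_%05d", seq_len(n)),
                      stringsAsFactors = FALSE)

  tps <- config$timepoints_h
  reps <- seq_len(config$n_reps)
  samples <- expand.grid(replicate = reps, timepoint_h = tps,
                         KEEP.OUT.ATTRS = FALSE)
  samples$condition <- ifelse(samples$timepoint_h == 0, "DMSO", "BETi")
  samples$sample_id <- sprintf("t%g_r%d", samples$timepoint_h,
                               samples$replicate)
  samples <- samples[, c("sample_id", "condition", "timepoint_h", "replicate")]

  mu <- stats::rlnorm(n, config$mean_expression_log_mu,
                      config$mean_expression_log_sigma)
  q_new <- 1 - (1 - config$conversion_rate)^config$n_T_sites
  q_old <- 1 - (1 - config$background_rate)^config$n_T_sites

  # per-gene nascent-rate log2fc per timepoint: 0 at reference, the "early"
  # lfc at the second timepoint, the "late" lfc at every later one
  lfc_by_tp <- cbind(0, lfcs[, 1],
                     matrix(rep(lfcs[, 2], max(0, length(tps) - 2)), nrow = n))

  size <- 1 / config$dispersion
  nsamp <- nrow(samples)
  total <- matrix(0L, n, nsamp, dimnames = list(gene_ids, samples$sample_id))
  labeled <- total
  for (j in seq_len(nsamp)) {
    tp_idx <- match(samples$timepoint_h[j], tps)
    tot_j <- stats::rnbinom(n, mu = mu, size = size)
    f <- pmin(1, pmax(0, config$baseline_new_fraction * 2^lfc_by_tp[, tp_idx]))
    p_lab <- f * q_new + (1 - f) * q_old
    lab_j <- stats::rbinom(n, tot_j, p_lab)
    total[, j] <- tot_j
    labeled[, j] <- lab_j
  }
  storage.mode(total) <- "integer"
  storage.mode(labeled) <- "integer"
  counts <- conversion_counts(gene_ids, samples, total, labeled)
  counts$labeling <- list(conversion_rate = config$conversion_rate,
                          background_rate = config$background_rate,
                          n_T_sites = config$n_T_sites)
  list(counts = counts, truth = truth)
}

#' Simulate per-region factor binding with planted compensation
#'
#' One regulatory region per gene in the truth table. Under treatment the
#' lost factor (BRD4) is depleted at every region by a global planted log2
#' delta; the gained factor (p300) increases only at regions linked to
#' rescued genes. Signals are log-normal around the planted means and are
#' reported as library-comparable coverage units.
#'
#' @param config a [sim_config()] (supplies the seed).
#' @param truth truth table from [simulate_timecourse_counts()].
#' @param delta_brd4 planted global log2 change of BRD4 signal under
#'   treatment (negative).
#' @param delta_p300_rescued planted log2 gain of p300 at rescued-linked
#'   regions.
#' @param noise_sd standard deviation (log2 scale) of replicate noise.
#' @param n_reps replicates per factor and condition.
#' @param n_chroms number of synthetic chromosomes to spread regions over.
#' @param region_halfwidth half the region width in bp.
#' @param seed optional seed; defaults to `config$seed + 1`.
#' @return a `region_signal` object: list with `regions` (region_id, chrom,
#'   start, end, linked_gene, true_delta_brd4, true_delta_p300), `signal`
#'   (long data frame: region_id, factor, condition, replicate, signal) and
#'   `tss` (gene_id, chrom, strand, tss_position) for annotation round-trips.
#' @export
simulate_binding <- function(config, truth,
                             delta_brd4 = -1.5,
                             delta_p300_rescued = 1.5,
                             noise_sd = 0.25,
                             n_reps = 2,
                             n_chroms = 5,
                             region_halfwidth = 500,
                             seed = NULL) {
  .assert(is.data.frame(truth) && nrow(truth) > 0,
          "truth must be a non-empty data frame")
  set.seed(seed %||% (config$seed + 1L))
  n <- nrow(truth)
  chrom <- paste0("chr", ((seq_len(n) - 1) %% n_chroms) + 1)
  idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  tss <- idx_on_chrom * 10000L
  regions <- data.frame(region_id = truth$linked_region_id,
                        chrom = chrom,
                        start = tss - region_halfwidth,
                        end = tss + region_halfwidth,
                        linked_gene = truth$gene_id,
                        true_delta_brd4 = delta_brd4,
                        true_delta_p300 = ifelse(truth$true_class == "rescued",
                                                 delta_p300_rescued, 0),
                        stringsAsFactors = FALSE)
  tss_table <- data.frame(gene_id = truth$gene_id, chrom = chrom,
                          strand = "+", tss_position = tss,
                          stringsAsFactors = FALSE)

  base <- stats::setNames(stats::rlnorm(2 * n, meanlog = 3, sdlog = 0.5),
                          NULL)
  base_brd4 <- base[seq_len(n)]
  base_p300 <- base[n + seq_len(n)]
  grid <- expand.grid(condition = c("DMSO", "BETi"),
                      replicate = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sig <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cond <- grid$condition[i]
    treated <- cond == "BETi"
    d_brd4 <- if (treated) regions$true_delta_brd4 else 0
    d_p300 <- if (treated) regions$true_delta_p300 else 0
    rbind(
      data.frame(region_id = regions$region_id, factor = "BRD4",
                 condition = cond, replicate = grid$replicate[i],
                 signal = base_brd4 * 2^(d_brd4 +
                                           stats::rnorm(n, 0, noise_sd)),
                 stringsAsFactors = FALSE),
      data.frame(region_id = regions$region_id, factor = "p300",
                 condition = cond, replicate = grid$replicate[i],
                 signal = base_p300 * 2^(d_p300 +
                                           stats::rnorm(n, 0, noise_sd)),
                 stringsAsFactors = FALSE))
  }))
  rownames(sig) <- NULL
  structure(list(regions = regions, signal = sig, tss = tss_table),
            class = "region_signal")
}

#' Simulate a dose-response matrix with a controllable interaction
#'
#' Monotherapy responses follow four-parameter Hill curves; combination
#' wells follow the Bliss-independence expectation on the percent-inhibition
#' scale plus a planted interaction (percentage points) plus Gaussian noise,
#' clipped to 0-100. The scheduling mode is recorded as a metadata label
#' only; the planted interaction is what differs between modes in practice.
#'
#' @param hill_a,hill_b lists with `bottom`, `top`, `ec50`, `slope` for the
#'   two drugs (percent-inhibition scale).
#' @param interaction_delta planted deviation from Bliss at combination wells
#'   (percentage points; positive = synergy).
#' @param mode scheduling label: `"BETi_first"`, `"concomitant"` or
#'   `"p300i_first"`.
#' @param doses_a,doses_b dose grids; must include 0 (vehicle).
#' @param noise_sd Gaussian noise SD (percentage points).
#' @param readout_day metadata: day of the viability readout.
#' @param seed integer seed.
#' @return a `dose_matrix` object: `doses_a`, `doses_b`, `inhibition` matrix
#'   (rows = doses_a, cols = doses_b), `mode`, `readout_day`.
#' @export
simulate_dose_matrix <- function(hill_a = list(bottom = 0, top = 100,
                                               ec50 = 400, slope = 1.2),
                                 hill_b = list(bottom = 0, top = 100,
                                               ec50 = 400, slope = 1.2),
                                 interaction_delta = 0,
                                 mode = c("BETi_first", "concomitant",
                                          "p300i_first"),
                                 doses_a = c(0, 50, 100, 200, 400),
                                 doses_b = c(0, 50, 100, 200, 400),
                                 noise_sd = 0,
                                 readout_day = 5,
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (!any(doses_a == 0) || !any(doses_b == 0))
    stop("dose grids must include 0 (vehicle)", call. = FALSE)
  .assert(all(doses_a >= 0) && all(doses_b >= 0), "doses must be nonnegative")
  set.seed(seed)
  ya <- hill_response(doses_a, hill_a)
  yb <- hill_response(doses_b, hill_b)
  # Bliss on the percent scale: y = yA + yB - yA*yB/100
  y <- outer(ya, yb, function(a, b) a + b - a * b / 100)
  combo <- outer(doses_a > 0, doses_b > 0, "&")
  y[combo] <- y[combo] + interaction_delta
  if (noise_sd > 0)
    y <- y + matrix(stats::rnorm(length(y), 0, noise_sd), nrow(y))
  y[] <- pmin(100, pmax(0, y))
  dimnames(y) <- list(dose_a = as.character(doses_a),
                      dose_b = as.character(doses_b))
  dose_matrix(doses_a, doses_b, y, mode = mode, readout_day = readout_day)
}

#' Simulate longitudinal resistance-stage expression from archetypes
#'
#' Genes are drawn from named temporal archetypes over the four resistance
#' stages (untreated, short-term treated, incipient and full resistance);
#' each gene's stage means are the archetype template scaled by a per-gene
#' amplitude on top of a baseline, plus Gaussian noise. Optionally emits a
#' paired arm with per-archetype, per-stage log2 shifts, emulating
#' measurement with and without a co-inhibitor.
#'
#' @param n_genes number of genes.
#' @param archetype_props named fractions over
#'   `evolution, degression, stress, inflammation, interferon, flat`;
#'   must sum to 1.
#' @param stage_labels names of the four ordered stages.
#' @param noise_sd Gaussian noise SD (expression units).
#' @param amplitude_range per-gene amplitude drawn uniformly from this range.
#' @param baseline baseline expression added to every stage.
#' @param paired_log2fc optional archetype-by-stage matrix of log2 shifts for
#'   a paired arm (rownames = archetypes, colnames = stages); when supplied
#'   the result carries a `paired` matrix.
#' @param deterministic_classes allocate archetypes deterministically
#'   (exact counts) instead of by multinomial sampling.
#' @param seed integer seed.
#' @return list with `profiles` (gene-by-stage matrix), `truth` (gene_id,
#'   archetype, amplitude) and optionally `paired`.
#' @export
simulate_resistance_course <- function(n_genes = 500,
                                       archetype_props = c(evolution = 0.20,
                                                           degression = 0.20,
                                                           stress = 0.15,
                                                           inflammation = 0.15,
                                                           interferon = 0.15,
                                                           flat = 0.15),
                                       stage_labels = c("DMSO", "BETi_72h",
                                                        "IC50_r", "IC90_r"),
                                       noise_sd = 0.25,
                                       amplitude_range = c(1, 3),
                                       baseline = 5,
                                       paired_log2fc = NULL,
                                       deterministic_classes = FALSE,
                                       seed = 1L) {
  templates <- archetype_templates()
  if (!all(names(archetype_props) %in% c(rownames(templates), "flat")))
    stop("unknown archetype name in archetype_props", call. = FALSE)
  .assert(abs(sum(archetype_props) - 1) <= 1e-9,
          "archetype_props must sum to 1")
  .assert(length(stage_labels) == 4, "exactly 4 stages are required")
  set.seed(seed)
  if (deterministic_classes) {
    counts <- floor(n_genes * archetype_props)
    rem <- n_genes - sum(counts)
    if (rem > 0) {
      frac <- n_genes * archetype_props - counts
      top <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1
    }
    arch <- rep(names(archetype_props), counts)
  } else {
    arch <- sample(names(archetype_props), n_genes, replace = TRUE,
                   prob = archetype_props)
  }
  amp <- stats::runif(n_genes, amplitude_range[1], amplitude_range[2])
  tmpl_full <- rbind(templates, flat = c(0, 0, 0, 0))
  means <- tmpl_full[arch, , drop = FALSE] * amp + baseline
  profiles <- means + matrix(stats::rnorm(n_genes * 4, 0, noise_sd), n_genes)
  gene_ids <- sprintf("rgene_%04d", seq_len(n_genes))
  dimnames(profiles) <- list(gene_ids, stage_labels)
  truth <- data.frame(gene_id = gene_ids, archetype = arch, amplitude = amp,
                      stringsAsFactors = FALSE)
  out <- list(profiles = profiles, truth = truth,
              stage_labels = stage_labels)
  if (!is.null(paired_log2fc)) {
    .assert(all(arch %in% rownames(paired_log2fc)) &&
              ncol(paired_log2fc) == 4,
            "paired_log2fc must cover all archetypes x 4 stages")
    shift <- paired_log2fc[arch, , drop = FALSE]
    paired <- means * 2^shift +
      matrix(stats::rnorm(n_genes * 4, 0, noise_sd), n_genes)
    dimnames(paired) <- dimnames(profiles)
    out$paired <- paired
  }
  out
}
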