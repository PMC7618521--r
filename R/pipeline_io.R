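# File formats, run configuration and the pipeline runner.

#' Read a count table (TSV or MatrixMarket)
#'
#' TSV layout: first column `gene_id`, then one column per sample; a sample
#' `S` may carry a paired `S.labeled` column with conversion counts. MTX
#' input is a plain triplet matrix; gene/sample ids come from sidecar files
#' `<path>.rownames` / `<path>.colnames` (one id per line) when present.
#'
#' @param path input file.
#' @param format `"tsv"` or `"mtx"`.
#' @param sample_sheet optional data frame (or TSV path) with `sample_id`,
#'   `condition`, `timepoint_h`, `replicate`; defaults are derived from the
#'   sample ids when absent.
#' @return a [conversion_counts()] object (labeled counts present only when
#'   `.labeled` columns exist).
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        sample_sheet = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
    gene_ids <- if (file.exists(rn)) readLines(rn)
    else sprintf("gene_%05d", seq_len(nrow(m)))
    sample_ids <- if (file.exists(cn)) readLines(cn)
    else sprintf("sample_%d", seq_len(ncol(m)))
    dimnames(m) <- list(gene_ids, sample_ids)
    tab <- data.frame(gene_id = gene_ids, m, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    .assert(names(tab)[1] == "gene_id", "first column must be gene_id")
  }
  gene_ids <- as.character(tab$gene_id)
  cols <- setdiff(names(tab), "gene_id")
  lab_cols <- grep("\\.labeled$", cols, value = TRUE)
  tot_cols <- setdiff(cols, lab_cols)
  tot <- as.matrix(tab[tot_cols])
  if (any(tot != round(tot))) stop("non-integer counts", call. = FALSE)
  storage.mode(tot) <- "integer"
  rownames(tot) <- gene_ids
  lab <- NULL
  if (length(lab_cols) > 0) {
    base <- sub("\\.labeled$", "", lab_cols)
    .assert(all(base %in% tot_cols),
            "every .labeled column needs a matching total column")
    lab <- matrix(0L, nrow(tot), ncol(tot),
                  dimnames = dimnames(tot))
    lm <- as.matrix(tab[lab_cols])
    if (any(lm != round(lm))) stop("non-integer counts", call. = FALSE)
    storage.mode(lm) <- "integer"
    lab[, base] <- lm
  }
  if (is.character(sample_sheet))
    sample_sheet <- utils::read.delim(sample_sheet, sep = "\t",
                                      comment.char = "#",
                                      stringsAsFactors = FALSE)
  samples <- if (!is.null(sample_sheet)) {
    .assert(all(tot_cols %in% sample_sheet$sample_id),
            "sample sheet must cover every sample column")
    sample_sheet[match(tot_cols, sample_sheet$sample_id), ]
  } else {
    data.frame(sample_id = tot_cols, condition = NA_character_,
               timepoint_h = NA_real_, replicate = NA_integer_,
               stringsAsFactors = FALSE)
  }
  conversion_counts(gene_ids, samples, tot, lab)
}

#' Write a conversion-count table as TSV
#'
#' Inverse of [read_counts()]; labeled counts become `<sample>.labeled`
#' columns.
#'
#' @param cc a [conversion_counts()] object.
#' @param path output path.
#' @param header_lines optional `#`-prefixed metadata lines.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cc, path, header_lines = character()) {
  tab <- data.frame(gene_id = cc$gene_ids, cc$total_counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cc$labeled_counts)) {
    lab <- cc$labeled_counts
    colnames(lab) <- paste0(colnames(lab), ".labeled")
    tab <- cbind(tab, lab)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0)
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read regions from a BED3+ file
#'
#' 0-based half-open intervals; an optional 4th column provides region ids
#' (auto-generated as `chrom:start-end` otherwise). Output is sorted by
#' (chrom, start); duplicate intervals are collapsed with a warning.
#'
#' @param path BED file path.
#' @return data frame `region_id, chrom, start, end`.
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("empty BED file", call. = FALSE)
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 3)) stop("malformed BED: fewer than 3 fields", call. = FALSE)
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED: non-numeric coordinates", call. = FALSE)
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop(sprintf("start >= end at line %d", bad[1]), call. = FALSE)
  region_id <- ifelse(nf >= 4, vapply(parts, function(p)
    if (length(p) >= 4) p[[4]] else NA_character_, character(1)),
    sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end)))
  df <- data.frame(region_id = region_id, chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[c("chrom", "start", "end")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate region(s)", sum(dup)))
    df <- df[!dup, ]
  }
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  df
}

#' Write regions as BED4
#'
#' @param regions data frame `region_id, chrom, start, end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "region_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' TSV with columns `gene_id, chrom, strand, tss_position` (0-based).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_tss_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  .assert(all(c("gene_id", "chrom", "tss_position") %in% names(tab)),
          "tss table needs gene_id/chrom/tss_position")
  tab
}

#' Read a dose matrix from TSV
#'
#' First row and first column hold the doses of drug B and drug A; cells are
#' percent inhibition.
#'
#' @param path TSV path.
#' @param mode,readout_day metadata for the resulting [dose_matrix()].
#' @return a [dose_matrix()].
#' @export
read_dose_matrix <- function(path, mode = "concomitant", readout_day = 5) {
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  doses_a <- as.numeric(tab[[1]])
  doses_b <- as.numeric(names(tab)[-1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  dose_matrix(doses_a, doses_b, m, mode = mode, readout_day = readout_day)
}

#' Pipeline run configuration
#'
#' @param stages stages to run, a subset of
#'   `simulate, quantify, rescue, chromatin, synergy, trajectory, report`,
#'   executed in that dependency order regardless of the order given.
#' @param sim a [sim_config()] for the simulate stage.
#' @param thresholds a [rescue_thresholds()].
#' @param interaction_deltas named planted interactions per scheduling mode
#'   for the synergy stage.
#' @param input_paths named list of external input files (checked to exist
#'   at validation); may be empty when simulating.
#' @param seed run seed; every stage derives a named substream from it.
#' @param data_type `"slam"`, `"rna"` or `"chip"`; selects which count layer
#'   the quantify stage tests.
#' @return a `run_config` list.
#' @export
run_config <- function(stages = c("simulate", "quantify", "rescue",
                                  "chromatin", "synergy", "trajectory",
                                  "report"),
                       sim = sim_config(),
                       thresholds = rescue_thresholds(),
                       interaction_deltas = c(BETi_first = 20,
                                              concomitant = 5,
                                              p300i_first = -5),
                       input_paths = list(),
                       seed = 1L,
                       data_type = c("slam", "rna", "chip")) {
  data_type <- match.arg(data_type)
  all_stages <- c("simulate", "quantify", "rescue", "chromatin", "synergy",
                  "trajectory", "report")
  .assert(all(stages %in% all_stages), "unknown stage name")
  for (p in input_paths)
    if (!file.exists(p)) stop(sprintf("input path does not exist: %s", p),
                              call. = FALSE)
  structure(list(stages = all_stages[all_stages %in% stages],
                 sim = sim, thresholds = thresholds,
                 interaction_deltas = interaction_deltas,
                 input_paths = input_paths,
                 seed = as.integer(seed), data_type = data_type),
            class = "run_config")
}

.write_stage_tsv <- function(df, path, version, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# betrescue %s", version),
               sprintf("# seed: %d", seed),
               sprintf("# config: %s", config_hash)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate, quantify, rescue, chromatin, synergy, trajectory, report),
#' writing one TSV (or JSON for nested synergy results) per stage into
#' `outdir`, each with a `#`-prefixed metadata header (version, seed,
#' config hash). Every stage draws randomness from its own named substream
#' of the run seed, so adding a stage does not perturb another stage's
#' draws. A manifest with per-file checksums is written and returned;
#' re-running with an identical config reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress per-stage log messages.
#' @return the run manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  version <- as.character(utils::packageVersion("betrescue"))
  chash <- .hash_object(unclass(config))
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character()
  state <- new.env(parent = emptyenv())

  need <- function(what, stage) {
    if (!exists(what, envir = state))
      stop(sprintf("missing upstream output '%s': run the '%s' stage first",
                   what, stage), call. = FALSE)
    get(what, envir = state)
  }
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    .write_stage_tsv(df, path, version, config$seed, chash)
    outputs <<- c(outputs, path)
    path
  }

  for (stage in config$stages) {
    if (stage == "simulate") {
      cfg <- config$sim
      cfg$seed <- .stage_seed(config$seed, "simulate")
      sim <- simulate_timecourse_counts(cfg)
      binding <- simulate_binding(cfg, sim$truth,
                                  seed = .stage_seed(config$seed,
                                                     "simulate_binding"))
      assign("counts", sim$counts, envir = state)
      assign("truth", sim$truth, envir = state)
      assign("binding", binding, envir = state)
      cpath <- file.path(outdir, "counts.tsv")
      write_counts(sim$counts, cpath,
                   header_lines = c(sprintf("betrescue %s", version),
                                    sprintf("seed: %d", config$seed),
                                    sprintf("config: %s", chash)))
      outputs <- c(outputs, cpath)
      emit(sim$truth, "truth.tsv")
      log_msg("[simulate] %d genes, %d samples",
              length(sim$counts$gene_ids), nrow(sim$counts$samples))
    } else if (stage == "quantify") {
      cc <- need("counts", "simulate")
      tps <- sort(unique(cc$samples$timepoint_h))
      dtype <- if (config$data_type == "slam") "slam" else "rna"
      d4 <- differential_timepoint(cc, tps[2], data_type = dtype)
      d24 <- differential_timepoint(cc, tps[length(tps)], data_type = dtype)
      assign("diff4", d4, envir = state)
      assign("diff24", d24, envir = state)
      emit(d4, "diff_early.tsv")
      emit(d24, "diff_late.tsv")
      log_msg("[quantify] tested %d / %d genes", sum(d4$tested), nrow(d4))
    } else if (stage == "rescue") {
      cls <- classify_rescue(need("diff4", "quantify"),
                             need("diff24", "quantify"),
                             config$thresholds)
      assign("classification", cls, envir = state)
      emit(cls, "classification.tsv")
      log_msg("[rescue] %d rescued / %d genes",
              sum(cls$class == "rescued"), nrow(cls))
    } else if (stage == "chromatin") {
      binding <- need("binding", "simulate")
      d_brd4 <- differential_binding(binding, "BRD4", depth_scale = FALSE)
      d_p300 <- differential_binding(binding, "p300", depth_scale = FALSE)
      comp <- compensation_score(d_brd4, d_p300)
      ann <- annotate_regions_to_genes(binding$regions, binding$tss)
      tab <- data.frame(region_id = d_brd4$region_id,
                        log2fc_brd4 = d_brd4$log2fc,
                        log2fc_p300 = d_p300$log2fc,
                        compensation = comp$score,
                        gene_id = ann$gene_id[match(d_brd4$region_id,
                                                    ann$region_id)],
                        stringsAsFactors = FALSE)
      assign("chromatin", tab, envir = state)
      emit(tab, "binding_deltas.tsv")
      log_msg("[chromatin] %d regions", nrow(tab))
    } else if (stage == "synergy") {
      res <- lapply(names(config$interaction_deltas), function(mode) {
        dmx <- simulate_dose_matrix(
          interaction_delta = config$interaction_deltas[[mode]],
          mode = mode, noise_sd = 0,
          seed = .stage_seed(config$seed, paste0("synergy_", mode)))
        zip_delta(dmx)
      })
      report <- compare_modes(res)
      assign("synergy", report, envir = state)
      jpath <- file.path(outdir, "synergy.json")
      jsonlite::write_json(
        list(version = version, seed = config$seed, config = chash,
             modes = lapply(res, function(r)
               list(mode = r$mode, mean_delta = r$mean_delta,
                    max_window_delta = r$max_window_delta, call = r$call,
                    delta_surface = r$delta_surface))),
        jpath, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, jpath)
      emit(report, "synergy_modes.tsv")
      log_msg("[synergy] %d modes scored", nrow(report))
    } else if (stage == "trajectory") {
      course <- simulate_resistance_course(
        seed = .stage_seed(config$seed, "trajectory"))
      var_genes <- select_variable_genes(course$profiles,
                                         min(100, nrow(course$profiles)))
      cl <- hierarchical_cluster(course$profiles[var_genes, ], k = 5)
      arch <- assign_archetypes(course$profiles)
      tab <- data.frame(gene_id = arch$gene_id, archetype = arch$archetype,
                        template_correlation = arch$template_correlation,
                        in_top_variable = arch$gene_id %in% var_genes,
                        cluster_id = ifelse(arch$gene_id %in% var_genes,
                                            cl[arch$gene_id], NA_integer_),
                        stringsAsFactors = FALSE)
      assign("trajectory", tab, envir = state)
      assign("trajectory_truth", course$truth, envir = state)
      emit(tab, "trajectory_modules.tsv")
      log_msg("[trajectory] %d genes, %d top-variable clustered",
              nrow(tab), length(var_genes))
    } else if (stage == "report") {
      cls <- need("classification", "rescue")
      truth <- need("truth", "simulate")
      merged <- merge(cls, truth, by = "gene_id")
      tp <- sum(merged$class == "rescued" &
                  merged$true_class == "rescued")
      summary <- data.frame(
        metric = c("n_genes", "n_rescued_called", "n_rescued_true",
                   "rescued_sensitivity", "rescued_fdr"),
        value = c(nrow(merged), sum(merged$class == "rescued"),
                  sum(merged$true_class == "rescued"),
                  tp / max(1, sum(merged$true_class == "rescued")),
                  1 - tp / max(1, sum(merged$class == "rescued"))),
        stringsAsFactors = FALSE)
      emit(summary, "report.tsv")
      log_msg("[report] rescued sensitivity %.3f",
              summary$value[summary$metric == "rescued_sensitivity"])
    }
  }
  manifest <- list(tool = "betrescue", version = version,
                   seed = config$seed, config_hash = chash,
                   outputs = lapply(stats::setNames(outputs,
                                                    basename(outputs)),
                                    function(p) unname(tools::md5sum(p))),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
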