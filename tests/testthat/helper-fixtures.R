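# Small simulation fixtures shared across test files.

small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 400, seed = seed, ...)
}

# noise-free-ish time course: tiny dispersion, many replicates
precise_config <- function(seed = 1, ...) {
  sim_config(n_genes = 300, dispersion = 1e-4, n_reps = 50,
             background_rate = 0, seed = seed, ...)
}

# deterministic region signal for chromatin tests
toy_region_signal <- function(n = 6, brd4_dmso = 10, brd4_beti = 10,
                              p300_dmso = 10, p300_beti = 10) {
  regions <- data.frame(region_id = sprintf("r%d", seq_len(n)),
                        chrom = "chr1",
                        start = seq_len(n) * 1000,
                        end = seq_len(n) * 1000 + 500,
                        stringsAsFactors = FALSE)
  grid <- expand.grid(region_id = regions$region_id,
                      factor = c("BRD4", "p300"),
                      condition = c("DMSO", "BETi"),
                      replicate = 1:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vals <- c(BRD4.DMSO = brd4_dmso, BRD4.BETi = brd4_beti,
            p300.DMSO = p300_dmso, p300.BETi = p300_beti)
  grid$signal <- vals[paste(grid$factor, grid$condition, sep = ".")]
  structure(list(regions = regions, signal = grid), class = "region_signal")
}
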