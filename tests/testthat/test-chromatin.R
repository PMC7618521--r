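test_that("nearest-TSS annotation handles distance, ties and cutoffs", {
  tss <- data.frame(gene_id = c("GENEA", "GENEB", "GENEC"),
                    chrom = c("chr1", "chr1", "chr2"),
                    tss_position = c(1000, 850, 500),
                    stringsAsFactors = FALSE)
  regions <- data.frame(region_id = c("r1", "r2", "r3", "r4"),
                        chrom = c("chr1", "chr1", "chr2", "chr3"),
                        start = c(900, 915, 1500500, 100),
                        end = c(950, 935, 1500600, 200),
                        stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_regions_to_genes(regions, tss,
                                                  max_distance_bp = 1e6),
                 "chr3")
  # r1 midpoint 925: distances 75 (GENEA) vs 75 (GENEB) -> tie -> GENEA
  expect_equal(ann$gene_id[1], "GENEA")
  expect_equal(ann$distance_to_tss[1], 75)
  # r2 midpoint 925: GENEB at 75 vs GENEA at 75... shifted window: mid 925
  expect_equal(ann$gene_id[2], "GENEA")
  # r3 midpoint 1500550: distance 1500050 > 1e6 -> unassigned
  expect_true(is.na(ann$gene_id[3]))
  expect_true(is.na(ann$gene_id[4]))
  # boundary: exactly max_distance is assigned, one past is not
  r <- data.frame(region_id = "b", chrom = "chr2",
                  start = 1000500 - 25, end = 1000500 + 25)
  expect_equal(annotate_regions_to_genes(r, tss, 1e6)$gene_id, "GENEC")
  r2 <- data.frame(region_id = "b", chrom = "chr2",
                   start = 1000501 - 25, end = 1000501 + 25)
  expect_true(is.na(annotate_regions_to_genes(r2, tss, 1e6)$gene_id))
})

test_that("differential binding handles identity, doubling and empty regions", {
  rs <- toy_region_signal(brd4_dmso = 10, brd4_beti = 10)
  d <- differential_binding(rs, "BRD4", depth_scale = FALSE)
  expect_true(all(d$log2fc == 0))
  rs2 <- toy_region_signal(p300_dmso = 10, p300_beti = 20)
  d2 <- differential_binding(rs2, "p300", pseudocount = 1e-9,
                             depth_scale = FALSE)
  expect_equal(d2$log2fc, rep(1, 6), tolerance = 1e-6)
  rs3 <- toy_region_signal(p300_dmso = 0, p300_beti = 0)
  d3 <- differential_binding(rs3, "p300", pseudocount = 1,
                             depth_scale = FALSE)
  expect_true(all(d3$log2fc == 0))
  expect_error(differential_binding(rs, "H3K27ac"), "not present")
})

test_that("compensation score follows its formula and antisymmetry", {
  rs <- toy_region_signal(brd4_dmso = 16, brd4_beti = 8,
                          p300_dmso = 8, p300_beti = 16)
  pc <- 1e-9
  d_brd4 <- differential_binding(rs, "BRD4", pseudocount = pc,
                                 depth_scale = FALSE)
  d_p300 <- differential_binding(rs, "p300", pseudocount = pc,
                                 depth_scale = FALSE)
  sc <- compensation_score(d_brd4, d_p300)
  expect_equal(sc$score, rep(2, 6), tolerance = 1e-6)
  sc_swapped <- compensation_score(d_p300, d_brd4)
  expect_equal(sc_swapped$score, -sc$score)
  expect_error(compensation_score(d_brd4, d_p300[1:3, ]), "region universe")
})

test_that("planted compensation at rescued regions is detectable", {
  detected <- sapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 600, seed = 100 + s)
    sim <- simulate_timecourse_counts(cfg)
    rs <- simulate_binding(cfg, sim$truth, seed = 200 + s)
    sc <- compensation_score(differential_binding(rs, "BRD4"),
                             differential_binding(rs, "p300"))
    rescued <- rs$regions$linked_gene %in%
      sim$truth$gene_id[sim$truth$true_class == "rescued"]
    wilcox.test(sc$score[rescued], sc$score[!rescued],
                alternative = "greater")$p.value < 0.01
  })
  expect_gte(sum(detected), 9)
})

test_that("top-fraction selection matches a brute-force oracle and nests", {
  set.seed(20)
  deltas <- data.frame(region_id = sprintf("r%04d", 1:1000),
                       log2fc = rnorm(1000, 0.5, 1),
                       stringsAsFactors = FALSE)
  top <- top_fraction_sites(deltas, 0.05)
  expect_length(top, 50)
  oracle <- deltas$region_id[order(-deltas$log2fc,
                                   deltas$region_id)][1:50]
  expect_equal(top, oracle)
  expect_true(all(top_fraction_sites(deltas, 0.01) %in%
                    top_fraction_sites(deltas, 0.05)))
  neg <- data.frame(region_id = c("a", "b"), log2fc = c(-1, 0))
  expect_warning(res <- top_fraction_sites(neg, 0.5), "truncated")
  expect_length(res, 0)
  expect_error(top_fraction_sites(deltas[0, ], 0.05), "empty")
})

test_that("concordance statistic matches toy arithmetic and maximal case", {
  deltas_b <- data.frame(region_id = paste0("r", 1:6),
                         log2fc = c(2, 2, 0, 0, 0, 0),
                         stringsAsFactors = FALSE)
  res <- cross_model_concordance(c("r1", "r2"), deltas_b, n_perm = 1000,
                                 seed = 1)
  expect_equal(res$shift_statistic, 2.0)
  # identical models: top set is B's own top -> minimal possible p
  set.seed(21)
  db <- data.frame(region_id = sprintf("r%04d", 1:500),
                   log2fc = rnorm(500), stringsAsFactors = FALSE)
  top <- top_fraction_sites(db, 0.05)
  res2 <- cross_model_concordance(top, db, n_perm = 1000, seed = 2)
  expect_equal(res2$p_perm, 1 / 1001)
  expect_error(cross_model_concordance("zzz", db), "shared")
})

test_that("metagene curves reproduce constant and ramp signals", {
  sig <- list(chr1 = rep(2, 10000))
  regions <- data.frame(chrom = "chr1", start = 4000, end = 4100)
  curve <- metagene_profile(sig, regions, flank_bp = 500, n_bins = 10)
  expect_equal(as.numeric(curve), rep(2, 10))
  # ramp: signal equal to position index
  sig2 <- list(chr1 = seq_len(10000))
  curve2 <- metagene_profile(sig2, regions, flank_bp = 500, n_bins = 10)
  expect_equal(diff(as.numeric(curve2)), rep(100, 9))
  # conservation: curve mean equals the window mean
  expect_equal(mean(curve2), mean(sig2$chr1[3551:4550]))
  # out-of-bounds windows are skipped and counted
  regions3 <- data.frame(chrom = "chr1", start = c(4000, 100),
                         end = c(4100, 200))
  curve3 <- metagene_profile(sig, regions3, flank_bp = 500, n_bins = 10)
  expect_equal(attr(curve3, "n_skipped"), 1)
})
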