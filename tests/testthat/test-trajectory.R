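test_that("variable-gene selection equals a brute-force variance sort", {
  set.seed(30)
  m <- matrix(rlnorm(500 * 4, 3, 1), 500,
              dimnames = list(sprintf("g%03d", 1:500), NULL))
  sel <- select_variable_genes(m, 100)
  expect_length(sel, 100)
  v <- apply(log2(m + 1), 1, var)
  oracle <- names(sort(v, decreasing = TRUE))[1:100]
  expect_setequal(sel, oracle)
  # perfect separation case
  m2 <- matrix(5, 200, 4, dimnames = list(sprintf("g%03d", 1:200), NULL))
  m2[1:100, ] <- m2[1:100, ] + outer(rep(1, 100), c(0, 2, 0, 2))
  expect_setequal(select_variable_genes(m2, 100),
                  sprintf("g%03d", 1:100))
  expect_error(select_variable_genes(m2, 201), "exceeds")
})

test_that("hierarchical clustering separates noise-free archetypes exactly", {
  rc <- simulate_resistance_course(
    n_genes = 100, noise_sd = 0, seed = 31, deterministic_classes = TRUE,
    archetype_props = c(evolution = 0.5, degression = 0.5))
  cl <- hierarchical_cluster(rc$profiles, k = 2)
  agree <- table(cl, rc$truth$archetype)
  expect_equal(sort(apply(agree, 1, max)), sort(rowSums(agree)))
  # degenerate: k = n gives singletons
  small <- rc$profiles[1:6, ] + matrix(rnorm(24, 0, 0.01), 6)
  expect_length(unique(hierarchical_cluster(small, k = 6)), 6)
})

test_that("constant profiles are adopted by their nearest neighbour", {
  rc <- simulate_resistance_course(
    n_genes = 60, noise_sd = 0.1, seed = 32, deterministic_classes = TRUE,
    archetype_props = c(evolution = 0.5, degression = 0.5))
  m <- rbind(rc$profiles, flatgene = c(5, 5, 5, 5))
  cl <- hierarchical_cluster(m, k = 2)
  expect_equal(attr(cl, "constant_genes"), "flatgene")
  expect_true(cl["flatgene"] %in% 1:2)
})

test_that("archetype assignment matches exact templates and floors noise", {
  m <- rbind(ev = c(1, 2, 3, 4), inf = c(5, 5, 9, 5),
             deg = c(9, 7, 5, 3), noise = c(5, 5.1, 4.9, 5))
  colnames(m) <- c("DMSO", "BETi_72h", "IC50_r", "IC90_r")
  asg <- assign_archetypes(m)
  expect_equal(asg$archetype[1:3], c("evolution", "inflammation",
                                     "degression"))
  expect_equal(asg$template_correlation[2], 1.0, tolerance = 1e-12)
  expect_error(assign_archetypes(m[, 1:3]), "4 ordered stages")
})

test_that("archetype assignment is invariant to affine transforms", {
  rc <- simulate_resistance_course(n_genes = 80, noise_sd = 0.2, seed = 33)
  a1 <- assign_archetypes(rc$profiles)
  a2 <- assign_archetypes(rc$profiles * 7 + 100)
  expect_equal(a1$archetype, a2$archetype)
})

test_that("archetypes are recovered from noisy data", {
  props <- c(evolution = 0.2, degression = 0.2, stress = 0.2,
             inflammation = 0.2, interferon = 0.2)
  rc0 <- simulate_resistance_course(n_genes = 200, noise_sd = 0, seed = 34,
                                    archetype_props = props)
  a0 <- assign_archetypes(rc0$profiles)
  expect_equal(mean(a0$archetype == rc0$truth$archetype), 1.0)
  rc <- simulate_resistance_course(n_genes = 400, noise_sd = 0.25,
                                   seed = 35, archetype_props = props)
  a <- assign_archetypes(rc$profiles)
  expect_gte(mean(a$archetype == rc$truth$archetype), 0.95)
})

test_that("stage summary reproduces construction and brute-force means", {
  shift <- matrix(0, 6, 4,
                  dimnames = list(c("evolution", "degression", "stress",
                                    "inflammation", "interferon", "flat"),
                                  c("DMSO", "BETi_72h", "IC50_r",
                                    "IC90_r")))
  shift["evolution", "IC90_r"] <- -1
  rc <- simulate_resistance_course(n_genes = 120, noise_sd = 0, seed = 36,
                                   paired_log2fc = shift,
                                   deterministic_classes = TRUE)
  asg <- data.frame(gene_id = rc$truth$gene_id,
                    archetype = rc$truth$archetype)
  s <- stage_response_summary(rc$profiles, rc$paired, asg)
  ev <- s[s$archetype == "evolution", ]
  expect_equal(ev$log2_ratio[ev$stage == "IC90_r"], -1, tolerance = 1e-9)
  expect_equal(ev$log2_ratio[ev$stage != "IC90_r"], rep(0, 3),
               tolerance = 1e-9)
  # brute-force group mean oracle
  rows <- rc$truth$archetype == "stress"
  expect_equal(s$mean[s$archetype == "stress" & s$stage == "BETi_72h"],
               mean(rc$profiles[rows, "BETi_72h"]))
  expect_error(stage_response_summary(rc$profiles, NULL, asg), "required")
})

test_that("gene-set blunting statistic separates constructed sets", {
  set.seed(37)
  lfc <- c(rnorm(50, -0.2, 0.1), rnorm(50, -1.0, 0.1), rnorm(20, 0, 0.1))
  names(lfc) <- sprintf("g%03d", seq_along(lfc))
  sets <- list(blunted = names(lfc)[1:50], deep = names(lfc)[51:100],
               tiny = names(lfc)[101:103])
  expect_warning(res <- geneset_delta(lfc, sets), "tiny")
  expect_equal(nrow(res$set_summary), 2)
  expect_equal(res$set_summary$mean_lfc[1] - res$set_summary$mean_lfc[2],
               0.8, tolerance = 0.1)
  p_ab <- res$pairwise$p_value[res$pairwise$set_A == "blunted"]
  expect_lt(p_ab, 0.01)
  # identical sets give a null test
  res2 <- geneset_delta(lfc, list(a = names(lfc)[1:50],
                                  b = names(lfc)[1:50]))
  expect_equal(res2$pairwise$mean_diff, c(0, 0))
  expect_true(all(abs(res2$pairwise$p_value - 0.5) < 0.05))
})
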