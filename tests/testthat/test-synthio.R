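test_that("sim_config validates its invariants", {
  expect_error(sim_config(class_proportions = c(rescued = 0.5,
                                                unchanged = 0.4)),
               "sum to 1")
  expect_error(sim_config(n_reps = 1), "n_reps")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(conversion_rate = 0.01, background_rate = 0.02),
               "background_rate")
})

test_that("deterministic class allocation gives exact counts", {
  cfg <- sim_config(n_genes = 5000,
                    class_proportions = c(rescued = 0.1, redundant = 0.15,
                                          induced = 0.05, unchanged = 0.7),
                    deterministic_classes = TRUE)
  sim <- simulate_timecourse_counts(cfg)
  expect_equal(sum(sim$truth$true_class == "rescued"), 500)
  expect_equal(sum(sim$truth$true_class == "redundant"), 750)
  expect_equal(nrow(sim$truth), 5000)
})

test_that("multinomial class frequencies track the configured proportions", {
  cfg <- sim_config(n_genes = 5000, seed = 11)
  sim <- simulate_timecourse_counts(cfg)
  obs <- table(factor(sim$truth$true_class,
                      levels = names(cfg$class_proportions)))
  gof <- chisq.test(obs, p = cfg$class_proportions)
  expect_gt(gof$p.value, 0.01)
})

test_that("time-course simulation is seed-deterministic", {
  a <- simulate_timecourse_counts(sim_config(n_genes = 100, seed = 42))
  b <- simulate_timecourse_counts(sim_config(n_genes = 100, seed = 42))
  expect_identical(a$counts$total_counts, b$counts$total_counts)
  expect_identical(a$counts$labeled_counts, b$counts$labeled_counts)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_timecourse_counts(sim_config(n_genes = 100, seed = 43))
  expect_false(identical(a$counts$total_counts, c2$counts$total_counts))
})

test_that("counts are nonnegative integers with labeled <= total", {
  sim <- simulate_timecourse_counts(small_config(seed = 2))
  expect_true(all(sim$counts$total_counts >= 0))
  expect_true(all(sim$counts$labeled_counts >= 0))
  expect_true(all(sim$counts$labeled_counts <= sim$counts$total_counts))
  expect_true(all(sim$counts$total_counts ==
                    round(sim$counts$total_counts)))
})

test_that("empirical lfc4 recovers planted truth at low noise", {
  cfg <- precise_config(seed = 3)
  sim <- simulate_timecourse_counts(cfg)
  d4 <- differential_timepoint(sim$counts, 4)
  m <- merge(d4, sim$truth, by = "gene_id")
  ok <- abs(m$lfc - m$true_lfc4) <= 0.1
  expect_gte(mean(ok), 0.95)
})

test_that("binding simulation plants global BRD4 loss and rescued-only p300 gain", {
  cfg <- sim_config(n_genes = 2000, seed = 5)
  sim <- simulate_timecourse_counts(cfg)
  rs <- simulate_binding(cfg, sim$truth)
  expect_true(all(rs$signal$signal >= 0))
  # planted deltas by construction
  expect_true(all(rs$regions$true_delta_brd4 < 0))
  unchanged <- rs$regions$linked_gene %in%
    sim$truth$gene_id[sim$truth$true_class == "unchanged"]
  expect_true(all(rs$regions$true_delta_p300[unchanged] == 0))
  # observed mean BRD4 delta near the planted -1.5 (no rescaling, tiny pc)
  d <- differential_binding(rs, "BRD4", depth_scale = FALSE,
                            pseudocount = 1e-6)
  expect_equal(mean(d$log2fc), -1.5, tolerance = 0.05)
  # seeded determinism
  rs2 <- simulate_binding(cfg, sim$truth)
  expect_identical(rs$signal, rs2$signal)
  expect_error(simulate_binding(cfg, sim$truth[0, ]), "non-empty")
})

test_that("dose matrix generator obeys the Bliss identity and grid layout", {
  dm <- simulate_dose_matrix(interaction_delta = 0, noise_sd = 0)
  ya <- dm$inhibition[, 1]
  yb <- dm$inhibition[1, ]
  expect_equal(dm$inhibition,
               outer(ya, yb, function(a, b) a + b - a * b / 100),
               ignore_attr = TRUE)
  # 4 dosages + vehicle per drug: 25 wells, 16 drug-drug combinations,
  # 8 monotherapy wells
  expect_equal(dim(dm$inhibition), c(5, 5))
  expect_equal(sum(outer(dm$doses_a > 0, dm$doses_b > 0, "&")), 16)
  expect_equal(sum(xor(outer(dm$doses_a > 0, rep(FALSE, 5), "|"),
                       outer(rep(FALSE, 5), dm$doses_b > 0, "|"))), 8)
  expect_error(simulate_dose_matrix(doses_a = c(1, 2, 3, 4)), "vehicle")
})

test_that("planted interaction adds percentage points at combo wells only", {
  d0 <- simulate_dose_matrix(interaction_delta = 0, noise_sd = 0)
  d20 <- simulate_dose_matrix(interaction_delta = 20, noise_sd = 0)
  expect_equal(d20$inhibition[1, ], d0$inhibition[1, ])
  expect_equal(d20$inhibition[, 1], d0$inhibition[, 1])
  expect_equal(d20$inhibition[-1, -1],
               pmin(100, d0$inhibition[-1, -1] + 20), ignore_attr = TRUE)
  # worked example: yA = yB = 50 -> bliss 75, +20 -> 95
  expect_equal(50 + 50 - 50 * 50 / 100 + 20, 95)
})

test_that("resistance course matches templates exactly at zero noise", {
  rc <- simulate_resistance_course(n_genes = 120, noise_sd = 0, seed = 9,
                                   deterministic_classes = TRUE)
  ev <- rc$profiles[rc$truth$archetype == "evolution", , drop = FALSE]
  expect_true(all(apply(ev, 1, function(x) all(diff(x) > 0))))
  inf <- rc$profiles[rc$truth$archetype == "inflammation", , drop = FALSE]
  expect_true(all(apply(inf, 1, which.max) == 3))
  expect_true(all(inf[, c(1, 2, 4)] == inf[, 1]))
  rc2 <- simulate_resistance_course(n_genes = 120, noise_sd = 0, seed = 9,
                                    deterministic_classes = TRUE)
  expect_identical(rc$profiles, rc2$profiles)
  expect_error(simulate_resistance_course(
    archetype_props = c(nonsense = 1)), "unknown archetype")
})
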