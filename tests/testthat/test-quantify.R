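test_that("median-of-ratios size factors are scale-equivariant", {
  set.seed(1)
  a <- matrix(rpois(600, 50), 100)
  same <- cbind(a[, 1], a[, 1], a[, 1])
  expect_equal(normalize_counts(same), rep(1, 3))
  doubled <- cbind(A = a[, 1], B = 2L * a[, 1])
  sf <- normalize_counts(doubled)
  expect_equal(sf[2] / sf[1], 2)
  expect_error(normalize_counts(matrix(0L, 5, 3)), "all-zero")
})

test_that("size factors stay near 1 for depth-balanced NB libraries", {
  set.seed(2)
  mu <- rlnorm(2000, 6, 1)
  cnt <- sapply(1:4, function(j) rnbinom(2000, mu = mu, size = 10))
  expect_true(all(normalize_counts(cnt) >= 0.9 &
                    normalize_counts(cnt) <= 1.1))
})

test_that("new-fraction estimator matches closed form and brute-force MLE", {
  # direct fraction when labeling is perfect and background absent
  expect_equal(estimate_new_fraction(1000, 300, conversion_rate = 0.9999,
                                     background_rate = 0, n_T_sites = 1e5),
               0.3, tolerance = 1e-4)
  expect_equal(estimate_new_fraction(500, 0, conversion_rate = 0.05,
                                     background_rate = 0), 0)
  # worked example: q_new = 0.6, q_old = 0.02, observed fraction 0.32
  cr <- 1 - (1 - 0.6)^(1 / 20)
  br <- 1 - (1 - 0.02)^(1 / 20)
  est <- estimate_new_fraction(10000, 3200, cr, br, 20)
  expect_equal(est, (0.32 - 0.02) / (0.6 - 0.02), tolerance = 1e-6)
  # independent oracle: grid-search MLE over the binomial mixture likelihood
  grid <- seq(0, 1, by = 1e-4)
  loglik <- dbinom(3200, 10000, grid * 0.6 + (1 - grid) * 0.02, log = TRUE)
  expect_equal(est, grid[which.max(loglik)], tolerance = 1e-3)
  expect_error(estimate_new_fraction(10, 20, 0.05), "labeled > total")
  expect_error(estimate_new_fraction(10, 5, 0.05, 0.05), "unidentifiable")
})

test_that("new-fraction estimator is consistent at deep coverage", {
  set.seed(3)
  q_new <- 1 - (1 - 0.05)^20
  q_old <- 1 - (1 - 0.001)^20
  truth <- runif(200, 0.05, 0.95)
  tot <- rep(1e4, 200)
  lab <- rbinom(200, tot, truth * q_new + (1 - truth) * q_old)
  est <- estimate_new_fraction(tot, lab, 0.05, 0.001, 20)
  expect_lt(mean(abs(est - truth)), 0.02)
})

test_that("differential test has exact null and swap antisymmetry", {
  set.seed(4)
  mu <- rlnorm(300, 6, 1)
  A <- sapply(1:3, function(j) rnbinom(300, mu = mu, size = 10))
  rownames(A) <- sprintf("g%03d", 1:300)
  counts <- cbind(A, A)
  colnames(counts) <- paste0("s", 1:6)
  sf <- rep(1, 6); names(sf) <- colnames(counts)
  d <- differential_test(counts, sf, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(all(d$lfc == 0))
  expect_true(all(d$p_value[d$tested] > 0.999))
  # swapping groups negates lfc and preserves p
  B <- sapply(1:3, function(j) rnbinom(300, mu = mu * 2, size = 10))
  counts2 <- cbind(A, B); colnames(counts2) <- paste0("s", 1:6)
  rownames(counts2) <- rownames(A)
  d_ab <- differential_test(counts2, sf, paste0("s", 1:3), paste0("s", 4:6))
  d_ba <- differential_test(counts2, sf, paste0("s", 4:6), paste0("s", 1:3))
  expect_equal(d_ab$lfc, -d_ba$lfc)
  expect_equal(d_ab$p_value, d_ba$p_value)
  expect_error(differential_test(counts, sf, "s1", paste0("s", 4:6)),
               ">= 2 replicates")
})

test_that("BH adjustment is monotone in p-rank and bounded by 1", {
  set.seed(5)
  mu <- rlnorm(500, 6, 1)
  cnt <- sapply(1:6, function(j) rnbinom(500, mu = mu, size = 10))
  rownames(cnt) <- sprintf("g%03d", 1:500)
  colnames(cnt) <- paste0("s", 1:6)
  sf <- normalize_counts(cnt); names(sf) <- colnames(cnt)
  d <- differential_test(cnt, sf, paste0("s", 1:3), paste0("s", 4:6))
  t_idx <- which(d$tested)
  ord <- t_idx[order(d$p_value[t_idx])]
  expect_true(all(diff(cummax(d$fdr[ord])) >= 0))
  expect_true(all(d$fdr[t_idx] <= 1))
  expect_true(all(d$fdr[t_idx] >= d$p_value[t_idx]))
  expect_true(all(is.na(d$fdr[!d$tested])))
})

test_that("differential test recovers a planted 4-fold decrease", {
  # with dispersion 0.1 the sampling sd of a 2-group lfc is ~sqrt(2a/n)/ln2,
  # so +-0.25 precision for >= 90% of genes needs ~20 replicates per group
  set.seed(6)
  n <- 400; reps <- 20
  mu <- rep(500, n)
  A <- sapply(seq_len(reps), function(j) rnbinom(n, mu = mu, size = 10))
  B <- sapply(seq_len(reps), function(j) rnbinom(n, mu = mu / 4, size = 10))
  cnt <- cbind(A, B)
  rownames(cnt) <- sprintf("g%03d", 1:n)
  colnames(cnt) <- paste0("s", 1:(2 * reps))
  sf <- rep(1, 2 * reps); names(sf) <- colnames(cnt)
  d <- differential_test(cnt, sf, paste0("s", 1:reps),
                         paste0("s", reps + 1:reps))
  expect_gte(mean(abs(d$lfc - (-2)) <= 0.25), 0.9)
  expect_gte(mean(d$fdr <= 0.05, na.rm = TRUE), 0.99)
})
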