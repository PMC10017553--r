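test_that("bootstrap mean difference matches an exhaustive enumeration", {
  a <- c(1, 2, 3)
  b <- a + 5
  # oracle: full enumeration of all 27 x 27 resamples at n = 3
  mean_a <- rowMeans(expand.grid(a, a, a))
  mean_b <- rowMeans(expand.grid(b, b, b))
  full <- as.vector(outer(mean_b, mean_a, "-"))
  ci_oracle <- stats::quantile(full, c(0.025, 0.975), names = FALSE)

  est <- bootstrap_mean_diff(a, b, n_boot = 20000, seed = 1)
  expect_equal(est$mean_diff, 5)
  expect_lt(abs(est$ci_low - ci_oracle[1]), 0.15)
  expect_lt(abs(est$ci_high - ci_oracle[2]), 0.15)
  expect_lte(est$ci_low, est$mean_diff)
  expect_gte(est$ci_high, est$mean_diff)

  # identical groups straddle zero
  z <- bootstrap_mean_diff(a, a, n_boot = 2000, seed = 2)
  expect_equal(z$mean_diff, 0)
  expect_lte(z$ci_low, 0)
  expect_gte(z$ci_high, 0)

  expect_error(bootstrap_mean_diff(1, c(1, 2)), "n >= 2")
})

test_that("bootstrap estimation is antisymmetric and seed-reproducible", {
  set.seed(10)
  a <- rnorm(12)
  b <- rnorm(12, 1)
  e1 <- bootstrap_mean_diff(a, b, n_boot = 10000, seed = 3)
  e2 <- bootstrap_mean_diff(b, a, n_boot = 10000, seed = 3)
  expect_equal(e2$mean_diff, -e1$mean_diff)
  expect_lt(abs(e2$ci_low + e1$ci_high), 0.1)
  expect_lt(abs(e2$ci_high + e1$ci_low), 0.1)
  e3 <- bootstrap_mean_diff(a, b, n_boot = 10000, seed = 3)
  expect_identical(e1$boot_dist, e3$boot_dist)
})

test_that("bootstrap CIs cover a small true difference at nominal rate", {
  # VMR-like scales: true diff 0.02, per-group n = 48
  n_rep <- 200
  covered <- logical(n_rep)
  set.seed(42)
  seeds <- sample.int(1e6, n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(seeds[i])
    a <- rnorm(48, 0.16, 0.07)
    b <- rnorm(48, 0.18, 0.07)
    e <- bootstrap_mean_diff(a, b, n_boot = 1000, seed = seeds[i])
    covered[i] <- e$ci_low <= 0.02 && 0.02 <= e$ci_high
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("exact rank-sum p-values come from full enumeration", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), mode = "exact"), 1 / 3)
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5), mode = "exact"), 1)
  # agreement with the reference implementation on untied data
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(5)
    b <- rnorm(6, 0.8)
    ours <- rank_sum_test(a, b, mode = "exact")
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_error(rank_sum_test(rnorm(8), rnorm(8), mode = "exact"),
               "n <= 12")
})

test_that("permutation p-values converge to the exact null", {
  a <- c(1.2, 3.4, 0.5, 2.2, 4.1)
  b <- c(5.3, 6.1, 4.9, 7.2, 5.8)
  p_exact <- rank_sum_test(a, b, mode = "exact")
  p_perm <- rank_sum_test(a, b, mode = "permutation", n_perm = 10000,
                          seed = 11)
  expect_lt(abs(p_perm - p_exact), 0.01)
  # asymptotic mode is sane on larger samples
  set.seed(12)
  x <- rnorm(30)
  y <- rnorm(30, 1.2)
  p_asy <- rank_sum_test(x, y, mode = "asymptotic")
  p_ref <- stats::wilcox.test(x, y, correct = TRUE)$p.value
  expect_lt(abs(p_asy - p_ref), 0.01)
})

test_that("relative expression ratios follow the efficiency model", {
  mk_ct <- function(tgt_ctl, tgt_trt, ref_ctl, ref_trt, e_t = 2, e_r = 2) {
    tibble::tibble(
      gene = rep(c("tgt", "ref"), each = length(tgt_ctl) + length(tgt_trt)),
      role = rep(c("target", "reference"),
                 each = length(tgt_ctl) + length(tgt_trt)),
      group = rep(rep(c("control", "treated"),
                      c(length(tgt_ctl), length(tgt_trt))), 2),
      ct = c(tgt_ctl, tgt_trt, ref_ctl, ref_trt),
      efficiency = rep(c(e_t, e_r),
                       each = length(tgt_ctl) + length(tgt_trt))
    )
  }
  # all delta-Ct zero -> ratio 1
  ct1 <- mk_ct(c(20, 20), c(20, 20), c(18, 18), c(18, 18))
  expect_equal(rest_ratio(ct1, "tgt", n_rand = 50, seed = 1)$ratio, 1)
  # one-cycle delay of the target halves expression at E = 2
  ct2 <- mk_ct(c(20, 20), c(21, 21), c(18, 18), c(18, 18))
  expect_equal(rest_ratio(ct2, "tgt", n_rand = 50, seed = 1)$ratio, 0.5)
  # reference-shift invariance: adding a constant to a reference gene's Cts
  # in both groups leaves the ratio unchanged
  ct3 <- mk_ct(c(20, 20.3), c(21.1, 20.9), c(18, 18.2), c(18.1, 17.9))
  ct3s <- ct3
  ct3s$ct[ct3s$gene == "ref"] <- ct3s$ct[ct3s$gene == "ref"] + 3
  r1 <- rest_ratio(ct3, "tgt", n_rand = 200, seed = 5)
  r2 <- rest_ratio(ct3s, "tgt", n_rand = 200, seed = 5)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  expect_equal(r1$p, r2$p)

  expect_error(rest_ratio(ct1[ct1$role == "target", ], "tgt"),
               "reference")
})

test_that("rest_ratio recovers simulated fold changes with a sound p-value", {
  genes <- c("18s", "tuba1a", "actb2", "drd3")
  fc <- c(`18s` = 1, tuba1a = 1, actb2 = 1, drd3 = 0.616)
  eff <- c(`18s` = 2, tuba1a = 2, actb2 = 2, drd3 = 2)
  refs <- c("18s", "tuba1a", "actb2")
  ct <- simulate_ct_table(genes, fc, eff, refs, n_reps = 9,
                          ct_noise_sd = 0.1, seed = 21)
  out <- rest_ratio(ct, "drd3", n_rand = 2000, seed = 22)
  expect_lt(abs(out$ratio - 0.616), 0.05)
  expect_lt(out$p, 0.05)
  # null target: fold 1 gives p spread away from 0
  fc0 <- c(`18s` = 1, tuba1a = 1, actb2 = 1, drd3 = 1)
  ct0 <- simulate_ct_table(genes, fc0, eff, refs, n_reps = 9,
                           ct_noise_sd = 0.1, seed = 23)
  out0 <- rest_ratio(ct0, "drd3", n_rand = 2000, seed = 24)
  expect_gt(out0$p, 0.05)
})
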