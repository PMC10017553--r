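test_that("trace simulation is deterministic and respects state supports", {
  p <- short_vmr()
  params <- locomotor_params()
  t1 <- simulate_trace(p, params, 42)
  t2 <- simulate_trace(p, params, 42)
  expect_identical(t1$speeds, t2$speeds)
  expect_equal(length(t1$speeds),
               round(protocol_duration(p) / params$frame_dt_s))

  # degenerate occupancies pin the chain
  no_burst <- locomotor_params(
    occupancy = cbind(light = c(0.6, 0.4, 0), dark = c(0.6, 0.4, 0)),
    startle_gain_on = 0, startle_gain_off = 0)
  tb <- simulate_trace(p, no_burst, 1)
  expect_true(all(tb$speeds < 20))

  all_inactive <- locomotor_params(
    occupancy = cbind(light = c(1, 0, 0), dark = c(1, 0, 0)))
  ti <- simulate_trace(p, all_inactive, 1)
  expect_true(all(ti$speeds == 0))

  # speed supports match the class thresholds
  only_coast <- locomotor_params(
    occupancy = cbind(light = c(0, 1, 0), dark = c(0, 1, 0)))
  tc <- simulate_trace(p, only_coast, 2)
  expect_true(all(tc$speeds > 0 & tc$speeds < 20))

  expect_error(locomotor_params(occupancy = cbind(light = c(0.5, 0.6, 0.2),
                                                  dark = c(1, 0, 0))),
               "summing to 1")
})

test_that("zero startle gains leave post-transition burst at baseline", {
  p <- short_vmr(n_trials = 1, pre_s = 120, epoch_s = 120)
  params <- locomotor_params(startle_gain_on = 0, startle_gain_off = 0,
                             occupancy = cbind(light = c(0.5, 0.45, 0.05),
                                               dark = c(0.5, 0.45, 0.05)),
                             dwell_s = cbind(light = c(0.8, 1.2, 0.3),
                                             dark = c(0.8, 1.2, 0.3)))
  n <- 200
  post <- pre <- numeric(n)
  for (i in seq_len(n)) {
    rec <- bin_activity(simulate_trace(p, params, i), 1)
    # 1 s windows just after and well before the ON transition at 120 s
    post[i] <- rec$dur_burst_s[rec$bin_start_s == 120]
    pre[i] <- rec$dur_burst_s[rec$bin_start_s == 60]
  }
  d <- mean(post) - mean(pre)
  se <- sqrt(stats::var(post) / n + stats::var(pre) / n)
  expect_lt(abs(d), 4 * se + 1e-12)
})

test_that("plate simulation records ground-truth nuisance multipliers", {
  p <- make_freeswim_protocol(1, 30, 10)
  gens <- list(wt_genotype(), ko_genotype())
  pl <- plate_spec(48, 0.1, c("b1", "b2"), 0.2)
  sim <- simulate_plate(p, gens, 48, pl, seed = 5)
  expect_equal(length(sim$traces), 96)
  expect_equal(nrow(sim$metadata), 96)
  expect_equal(sort(unique(sim$metadata$genotype)), c("KO", "WT"))
  expect_equal(as.numeric(table(sim$metadata$genotype)), c(48, 48))

  # determinism
  sim2 <- simulate_plate(p, gens, 48, pl, seed = 5)
  expect_identical(sim$metadata, sim2$metadata)
  expect_identical(sim$traces[[10]]$speeds, sim2$traces[[10]]$speeds)

  # no nuisance variation -> multipliers exactly 1
  pl0 <- plate_spec(48, 0, "b1", 0)
  sim0 <- simulate_plate(p, gens, 24, pl0, seed = 1)
  expect_true(all(sim0$metadata$well_mult == 1))
  expect_true(all(sim0$metadata$batch_mult == 1))

  expect_error(simulate_plate(p, gens, 49, pl0, seed = 1), "capacity")
})

test_that("biometry draws recover cohort moments and correlation", {
  g <- wt_genotype()
  b <- simulate_biometry(26, g, seed = 8)
  se <- g$biometry_sds[["lens_radius_um"]] / sqrt(26)
  expect_lt(abs(mean(b$lens_radius_um) - 362.12), 3 * se)
  expect_true(all(b$lens_radius_um > 0))

  # independent draws at corr = 0
  g0 <- g
  g0$biometry_corr <- 0
  b0 <- simulate_biometry(10000, g0, seed = 9)
  expect_lt(abs(stats::cor(b0$lens_radius_um, b0$retinal_radius_um)), 0.03)

  # strong correlation propagates
  g9 <- g
  g9$biometry_corr <- 0.9
  b9 <- simulate_biometry(10000, g9, seed = 10)
  expect_gt(stats::cor(b9$lens_radius_um, b9$retinal_radius_um), 0.85)

  # zero SDs give the mean vector
  gd <- g
  gd$biometry_sds[] <- 0
  bd <- simulate_biometry(5, gd, seed = 1)
  expect_true(all(bd$lens_radius_um == 362.12))
  expect_true(all(bd$retinal_radius_um == 717.52))
})

test_that("morphometry triplicates behave and recover input means", {
  means <- c(body_mm = 3.84, head_mm = 0.70, midbrain_mm = 0.52)
  sds <- c(body_mm = 0.26, head_mm = 0.044, midbrain_mm = 0.013)
  m0 <- simulate_morphometry(5, means, sds, replicate_sd = 0, seed = 2)
  expect_equal(m0$body_mm_1, m0$body_mm_2)
  expect_equal(m0$head_mm_2, m0$head_mm_3)

  m <- simulate_morphometry(19, means, sds, replicate_sd = 0.02, seed = 3)
  avg <- average_triplicate(m)
  for (tr in names(means)) {
    se <- sds[[tr]] / sqrt(19)
    expect_lt(abs(mean(avg[[tr]]) - means[[tr]]), 3 * se + 0.02)
  }
  expect_identical(m, simulate_morphometry(19, means, sds, 0.02, seed = 3))
})

test_that("Ct tables encode fold changes through efficiency shifts", {
  genes <- c("ref1", "tgt")
  fc <- c(ref1 = 1, tgt = 1)
  eff <- c(ref1 = 2, tgt = 2)
  ct0 <- simulate_ct_table(genes, fc, eff, "ref1", n_reps = 3,
                           ct_noise_sd = 0, seed = 1)
  ctl <- ct0$ct[ct0$group == "control"]
  trt <- ct0$ct[ct0$group == "treated"]
  expect_equal(ctl, trt)

  fc2 <- c(ref1 = 1, tgt = 0.5)
  ct2 <- simulate_ct_table(genes, fc2, eff, "ref1", n_reps = 3,
                           ct_noise_sd = 0, seed = 1)
  tgt <- ct2[ct2$gene == "tgt", ]
  expect_equal(mean(tgt$ct[tgt$group == "treated"]) -
                 mean(tgt$ct[tgt$group == "control"]), 1)

  expect_error(simulate_ct_table(genes, c(ref1 = 1, tgt = -2), eff, "ref1"),
               "> 0")
  expect_error(simulate_ct_table(genes, fc, c(ref1 = 0.9, tgt = 2), "ref1"),
               "> 1")
  expect_error(simulate_ct_table(genes, c(ref1 = 2, tgt = 1), eff, "ref1"),
               "reference")
})

test_that("colour-maze counts are multinomial with fixed totals", {
  w <- c(B = 41.18, R = 17.35, G = 18.94, Y = 18.53)
  cm <- simulate_color_maze(20, w, 18, seed = 4)
  expect_equal(nrow(cm), 18)
  expect_true(all(rowSums(cm[, names(w)]) == 20))

  one <- simulate_color_maze(20, c(B = 1, R = 0, G = 0, Y = 0), 10, seed = 1)
  expect_true(all(one$B == 20))
  expect_true(all(one[, c("R", "G", "Y")] == 0))

  eq <- simulate_color_maze(20, c(B = 1, R = 1, G = 1, Y = 1), 2000, seed = 2)
  pct <- colMeans(eq[, c("B", "R", "G", "Y")]) / 20 * 100
  expect_true(all(abs(pct - 25) < 1.5))

  expect_error(simulate_color_maze(25, w, 5, seed = 1), "20")
  expect_error(simulate_color_maze(10, c(B = 0, R = 0), 5, seed = 1),
               "not all zero")
})
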