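test_that("percent_response reproduces the printed flash responses", {
  # printed pre/post burst-duration means, 1000 ms and 10 ms cues
  expect_equal(round(percent_response(0.0046, 0.0082)), 178)
  expect_equal(round(percent_response(0.0045, 0.0062)), 138)
  expect_equal(round(percent_response(0.0052, 0.0058)), 112)
  expect_equal(percent_response(0.3, 0.3), 100)
  expect_equal(percent_response(0.4, 0), 0)
  expect_true(is.na(percent_response(0, 0.01)))
  # scale invariance
  for (k in c(0.1, 3, 1e4)) {
    expect_equal(percent_response(k * 0.0046, k * 0.0082),
                 percent_response(0.0046, 0.0082))
  }
  expect_error(percent_response(-1, 2), ">= 0")
})

test_that("vmr_response averages trials per larva and excludes gaps", {
  p <- short_vmr(n_trials = 2, pre_s = 60, epoch_s = 60)
  # larva bursting exactly 0.16 s in every bin
  rec <- rbind(constant_records(p, "w1", "WT", 0.16),
               constant_records(p, "w2", "KO", 0.30))
  r_on <- vmr_response(rec, p, "ON", window_s = 1)
  expect_equal(sort(r_on$per_larva$value), c(0.16, 0.30))
  expect_equal(r_on$summary$n, c(1, 1))

  # all-inactive records give 0
  rec0 <- constant_records(p, "w1", "WT", 0)
  expect_equal(vmr_response(rec0, p, "ON")$per_larva$value, 0)

  # saturation: window covering a whole ON epoch of constant burst
  rec1 <- constant_records(p, "w1", "WT", 1)
  r_full <- vmr_response(rec1, p, "ON", window_s = 60)
  expect_equal(r_full$per_larva$value, 60)

  # consistency limit: full-epoch window equals the epoch mean burst x epoch
  expect_equal(r_full$per_larva$value,
               mean(rec1$dur_burst_s) * 60)

  # missing bins in the window exclude the larva with a warning
  holed <- rec[!(rec$well_id == "w2" & rec$bin_start_s == 60), ]
  expect_warning(r_h <- vmr_response(holed, p, "ON"), "excluded")
  expect_equal(r_h$per_larva$well_id, "w1")

  expect_error(vmr_response(rec, make_freeswim_protocol(2, 30, 1), "ON"),
               "no ON transitions")
})

test_that("fstr_response computes pre/post windows and averages fwd/rev", {
  p_f <- make_fstr_protocol(c(1000), rest_min = 2, order = "forward",
                            pre_dark_min = 1)
  # flash at 60 s; burst 0.0046 s/bin before, 0.0082 s/bin after
  n_bins <- protocol_duration(p_f)  # bin_s = 1
  mk <- function(well, geno, pre_rate, post_rate) {
    r <- constant_records(p_f, well, geno, pre_rate)
    r$dur_burst_s[r$bin_start_s >= 60] <- post_rate
    r
  }
  rec <- mk("w1", "WT", 0.0046, 0.0082)
  out <- fstr_response(rec, p_f, window_s = 30)
  expect_equal(out$per_larva$pre_s, 30 * 0.0046, tolerance = 1e-12)
  expect_equal(out$per_larva$post_s, 30 * 0.0082, tolerance = 1e-12)
  expect_equal(round(out$per_larva$percent), 178)

  # forward and reverse runs average per larva; order must not matter
  p_r <- make_fstr_protocol(c(1000), rest_min = 2, order = "reverse",
                            pre_dark_min = 1)
  rec_r <- mk("w1", "WT", 0.0082, 0.0046)  # weaker response in reverse run
  out_fr <- fstr_response(list(rec, rec_r), list(p_f, p_r), window_s = 30)
  out_rf <- fstr_response(list(rec_r, rec), list(p_r, p_f), window_s = 30)
  expect_equal(out_fr$per_larva, out_rf$per_larva)
  expect_equal(out_fr$per_larva$pre_s, 30 * mean(c(0.0046, 0.0082)))

  # overlapping windows are a protocol misconfiguration
  p_tight <- make_fstr_protocol(c(1000, 1000), rest_min = 0.25,
                                pre_dark_min = 1)
  rec_t <- constant_records(p_tight, "w1", "WT", 0.01)
  expect_error(fstr_response(rec_t, p_tight, window_s = 30), "overlap")
})

test_that("freeswim_summary reports per-10s distances and class durations", {
  p <- make_freeswim_protocol(5, 30, 10)
  tr <- speed_trace("w1", "WT", "b1", 0.1, rep(10, 3000))
  rec <- bin_activity(tr, 10)
  fs <- freeswim_summary(rec, "light")
  expect_equal(fs$distance$per_larva$value, 100, tolerance = 1e-9)
  expect_equal(fs$coast_duration$per_larva$value, 10)
  expect_equal(fs$burst_duration$per_larva$value, 0)
  expect_match(fs$distance$assay, "light")

  # distances rescale to a 10 s denominator for other bin lengths
  rec1 <- bin_activity(tr, 1)
  fs1 <- freeswim_summary(rec1, "light")
  expect_equal(fs1$distance$per_larva$value, 100, tolerance = 1e-9)

  expect_error(freeswim_summary(rec[0, ], "light"), "no records")
})

test_that("colour preference percentages follow the count table", {
  cm <- simulate_color_maze(20, c(B = 1, R = 0, G = 0, Y = 0), 10, seed = 1)
  cp <- color_preference(cm, 20)
  expect_equal(cp$percent[cp$arm == "B"], 100)
  expect_equal(sum(cp$percent), 100)

  flat <- tibble::tibble(timepoint = 1:3, B = 5, R = 5, G = 5, Y = 5)
  cpf <- color_preference(flat, 20)
  expect_true(all(cpf$percent == 25))

  # neutral-centre variant: row sums below n_fish are allowed
  two <- tibble::tibble(timepoint = 1:2, B = 10, N = 8)
  cp2 <- color_preference(two, 20)
  expect_equal(cp2$percent, c(50, 40))

  bad <- tibble::tibble(timepoint = 1, B = 15, R = 10, G = 0, Y = 0)
  expect_error(color_preference(bad, 20), "exceed")
})

test_that("group summaries report mean, SEM and n per genotype", {
  pl <- tibble::tibble(well_id = sprintf("w%d", 1:6),
                       genotype = rep(c("WT", "KO"), each = 3),
                       value = c(1, 2, 3, 4, 5, 6))
  rs <- response_summary(pl, "demo")
  expect_equal(sort(rs$summary$genotype), c("KO", "WT"))
  wt <- rs$summary[rs$summary$genotype == "WT", ]
  expect_equal(wt$mean, 2)
  expect_equal(wt$sem, stats::sd(1:3) / sqrt(3))
  expect_equal(wt$n, 3)
})
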