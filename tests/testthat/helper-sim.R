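# Shared fixtures: desk-scale protocols and a random-trace generator.

# short VMR-like schedule: pre-dark then n_trials of ON/OFF cycles
short_vmr <- function(n_trials = 2, pre_s = 60, epoch_s = 120,
                      on_pct = 30, bin_s = 1) {
  durs <- c(pre_s, rep(epoch_s, 2 * n_trials))
  ints <- c(0, rep(c(on_pct, 0), n_trials))
  assay_protocol(
    "vmr_short",
    tibble::tibble(start_s = cumsum(c(0, durs[-length(durs)])),
                   duration_s = durs, intensity_pct = ints),
    bin_s = bin_s
  )
}

# random speed trace mixing zeros, coast and burst speeds
random_trace <- function(n_frames, seed, frame_dt_s = 0.1) {
  set.seed(seed)
  v <- sample(c(0, stats::runif(1, 0.5, 19.5), stats::runif(1, 20, 60)),
              n_frames, replace = TRUE,
              prob = c(0.5, 0.4, 0.1))
  speed_trace("w01", "WT", "b1", frame_dt_s, v)
}

# records for a constant-burst larva: dur_burst_s = value in every bin
constant_records <- function(protocol, well_id, genotype, burst_s,
                             bin_s = protocol$bin_s) {
  n_bins <- protocol_duration(protocol) / bin_s
  tibble::tibble(
    well_id = well_id, genotype = genotype, batch = "b1",
    bin_start_s = (seq_len(n_bins) - 1) * bin_s, bin_s = bin_s,
    dur_inactive_s = bin_s - burst_s, dur_coast_s = 0,
    dur_burst_s = burst_s, dist_coast_mm = 0,
    dist_burst_mm = burst_s * 30, n_bouts_coast = 0,
    n_bouts_burst = as.numeric(burst_s > 0)
  )
}
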