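# swimbout

Quantification of visually guided locomotor behaviour and ocular biometry
in larval zebrafish.

Plate-based video tracking (Zebrabox-style enclosures) reports each
larva's swim speed per frame or per acquisition bin. Zebrafish larvae swim
in a **burst-glide** style — slow coasting (0–20 mm/s) and inactivity
punctuated by fast bursts (≥ 20 mm/s) — and their visually evoked startle
responses are read out as changes in **burst duration** around light
transitions. `swimbout` implements that whole analysis path for
behavioural neuroscience and ophthalmology labs working with larval
zebrafish:

* **Bout analysis** — classify speeds into inactive / coast / burst,
  segment bouts, aggregate to binned activity records
  (`classify_speed()`, `segment_bouts()`, `bin_activity()`).
* **Protocols** — illumination schedules whose transitions anchor analysis
  windows: visual motor response (VMR; 30 min light-ON/OFF cycles), flash
  stimulus threshold response (FSTR; 10–1000 ms cues with 20 min rests),
  constant-light free swim (`make_vmr_protocol()`, `make_fstr_protocol()`,
  `make_freeswim_protocol()`, `transitions()`).
* **Normalization** — the three-step correction for per-well illumination,
  batch, and baseline activity (`normalize_activity()`).
* **Assay statistics** — per-larva then group mean ± SEM:
  `vmr_response()` (burst duration 1 s after a transition),
  `fstr_response()` / `percent_response()` (post-flash burst as a percent
  of pre-flash, `100·post/pre`), `freeswim_summary()`,
  `color_preference()`.
* **Ocular biometry** — lens circularity ratio, axial length normalized by
  body length, and the relative refractive error
  `RRE = 1 − retinal radius / (2.324 · lens radius)` (positive =
  hyperopic), plus triplicate-averaged morphometric ratios
  (`rre()`, `derive_ocular_metrics()`, `morpho_ratios()`).
* **Resampling statistics** — Gardner–Altman-style bootstrap
  mean-difference estimation with percentile 95% CIs
  (`bootstrap_mean_diff()`), exact/permutation/asymptotic rank-sum tests
  (`rank_sum_test()`), and efficiency-corrected relative expression with a
  label-reallocation randomization test (`rest_ratio()`).
* **Simulator** — a calibrated stochastic burst-glide locomotion model
  (Markov dwell-time chain with a startle kernel on the burst weight) and
  samplers for biometry, morphometry, qPCR Ct tables, and colour-maze
  counts (`simulate_trace()`, `simulate_plate()`, `simulate_biometry()`,
  `simulate_ct_table()`, `simulate_color_maze()`).

See the methods vignette (`vignettes/swimbout-methods.Rmd`) for the model,
its assumptions, calibration, and limitations.

## Worked example

```r
library(swimbout)

# the standard VMR schedule: 30 min dark, then 3 x (30 min ON / 30 min OFF)
protocol <- make_vmr_protocol(n_trials = 3, on_intensity_pct = 30,
                              pre_dark_min = 30, bin_s = 1)
protocol
#> <assay_protocol> vmr: 7 epochs, 12600.0 s total, bin 1 s

# simulate a two-batch free-swim experiment, 48 larvae per genotype
plate <- plate_spec(n_wells = 48, well_light_sd = 0.1,
                    batch_ids = c("b1", "b2"), batch_effect_sd = 0.2)
sim <- simulate_plate(make_freeswim_protocol(5, 30, 10),
                      list(wt_genotype(), ko_genotype()),
                      n_per_genotype = 48, plate, seed = 11)
records <- do.call(rbind, lapply(sim$traces, bin_activity, bin_s = 10))
freeswim_summary(records, "light")$distance
#> <response_summary> freeswim_light_dist_mm_per_10s
#> # A tibble: 2 x 4
#>   genotype  mean   sem     n
#>   <chr>    <dbl> <dbl> <dbl>
#> 1 KO        34.5 1.21     48
#> 2 WT        33.2 0.879    48
```

Both genotypes swim ~28–35 mm per 10 s under constant light, and the
wild-type group mean lands on the calibration target (≈ 34 mm/10 s). The
biometric and flash-response helpers work directly on measured values:

```r
round(rre(362.12, 717.52), 4)         # wild-type cohort means (um)
#> [1] 0.1474
round(rre(351.15, 643.52), 4)         # knock-out cohort means: hyperopic shift
#> [1] 0.2114
morpho_ratios(3.84, 0.70, 0.52)       # body, head, midbrain (mm)
#> # A tibble: 1 x 2
#>   head_to_body head_to_midbrain
#>          <dbl>            <dbl>
#> 1        0.182            0.743
round(percent_response(0.0046, 0.0082))  # pre/post flash burst (s) -> percent
#> [1] 178
```

A positive RRE marks a hyperopic eye (retina closer than the idealized
focal length); the knock-out's larger RRE is a hyperopic shift. The flash
response of 178% means post-stimulus burst activity was 1.78× the
pre-stimulus level.

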