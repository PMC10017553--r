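---
title: "Methods: burst-glide bout analysis, visual assay statistics, and ocular biometry"
author: "swimbout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst-glide bout analysis, visual assay statistics, and ocular biometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimbout)
```

## Scope

`swimbout` quantifies visually guided locomotor behaviour of larval
zebrafish from plate-based video-tracking exports, and the ocular/body
geometry that accompanies such studies. The pipeline is:

1. **Protocols** — illumination schedules (`assay_protocol`) whose light
   transitions anchor analysis windows.
2. **Bout analysis** — classify per-frame swim speeds into *inactive*
   (0 mm/s), *coast* (0–20 mm/s), and *burst* (≥ 20 mm/s), segment bouts,
   and aggregate into binned activity records.
3. **Normalization** — a three-step correction for well illumination,
   batch, and baseline activity.
4. **Assays** — the response statistics: VMR transition responses, FSTR
   flash percent responses, free-swim summaries, colour-maze preferences.
5. **Biometry** — lens ratio, normalized axial length, relative refractive
   error (RRE), and morphometric ratios.
6. **Statistics** — bootstrap mean-difference estimation, rank-sum tests,
   and efficiency-corrected relative expression with a randomization test.
7. **Simulator** — a stochastic burst-glide locomotion model plus samplers
   for biometry, morphometry, Ct tables, and maze counts, so every stage
   has a self-contained, seed-reproducible test surface.

## Activity classes and bouts

Speeds are classified with the 0 and 20 mm/s thresholds. The boundary value
20 mm/s is assigned to **burst**: the fast class is described as
"at or above" threshold in the behavioural literature this package follows,
and a closed burst class keeps the headline burst statistic well defined.
Both the threshold (`coast_max_mm_s`) and its inclusivity
(`burst_inclusive`) are arguments.

A *bout* is a maximal run of frames in one class. Binned records report
per-class durations (frames × frame interval), per-class distances
(speed × frame interval, summed), and bout counts attributed to the bin
containing the bout's first frame. Three invariants are enforced by tests:
durations partition each bin exactly; distances are conserved to 1e-9 mm;
and 1 s records aggregate exactly to 10 s records.

## Protocols and the time origin

Time zero is the start of the recording. Pre-recording adaptation (2 h in
the standard assays) contributes no epochs; it is carried as metadata
(`adaptation_s`, `adaptation_pct`). Only the in-recording pre-illumination
period (e.g. 30 min before the first ON transition of the VMR assay) is an
epoch. When the adaptation illumination differs from the first epoch's
intensity — a dark-adapted larva meeting a lit first epoch — the recording
opens with a transition at t = 0.

Intensity is percent of the enclosure maximum (100% ≡ 8,000 lux nominal)
and is mapped linearly when lux are needed; only relative percent is used
downstream. Epoch boundaries must land on the acquisition-bin grid, except
for flash protocols: a 10 ms cue cannot land on a 1 s grid, so FSTR
protocols relax that check and the analysis snaps windows to the bin grid
(floor of the flash time). The VMR assay supports 2 or 3 trials ("two to
three" in the source protocols); the default is 3, which matches the 3.5 h
standard tracking duration.

## The burst-glide simulator

The latent activity state evolves as a discrete-time Markov chain with
state-specific mean dwell times: at each frame (default `frame_dt_s`
= 0.1 s) the chain leaves its state with probability
`frame_dt_s / dwell`, and on a switch draws the next state from
illumination-conditional occupancy weights. Dwell-time dynamics (rather
than i.i.d. per-frame states) make bout durations well defined and roughly
geometric. The chain's stationary shares are proportional to
weight × dwell.

A light transition multiplies the burst weight by
`1 + gain · exp(-Δt / startle_decay_s)` with direction-specific gains;
the kernel of the most recent transition is used (inter-transition gaps in
all supported protocols are minutes, far exceeding the 1 s decay constant,
so kernel overlap is negligible). Speeds are drawn per frame from the
current state's distribution: 0 for inactive, `20 · Beta(2, 4.5)` mm/s for
coast, `20 + Gamma(shape 2, scale 7.5)` mm/s for burst — bounded supports
matching the class definitions.

**Calibration.** Defaults reproduce the wild-type study conditions:
free-swim distances ≈ 33.9 mm/10 s (light) and 28.4 mm/10 s (dark), a
light-ON VMR response of ≈ 0.167 s burst within 1 s of the transition, and
a light-OFF response of ≈ 0.274 s. The knock-out configuration encodes the
reported effect directions: light-ON startle gain ×1.125 (hyperactive ON
response), dark coast dwell ×0.79 (reduced dark coast duration), and a
mesopic variant with gain ×0.95 (reversal under rod recruitment). The
printed coast durations in the source study (≈ 35 vs 31 s) have an
unstated denominator and are treated as *relative* calibration only; with
a single illumination-independent coast-speed distribution the simulator
reproduces the light>dark distance ordering, not the within-genotype
coast-duration ordering — a documented limitation.

What the simulator does *not* emulate: habituation, circadian drift,
positional/thigmotaxis structure, sub-second startle latency, retinal
circuitry. Passing recovery tests therefore demonstrate the pipeline's
correctness on data obeying the stated generative model, not robustness to
every artefact of real recordings.

Nuisance variation mirrors the three normalization causes: a per-well
received-light multiplier (log-normal, relative SD `well_light_sd`), a
per-batch activity multiplier (log-normal, `batch_effect_sd`), both acting
multiplicatively on speed and recorded as ground truth in the plate
metadata. Millisecond flashes are rendered by one partial-frame intensity
sample at the default 0.1 s frame — cues of 10–50 ms are visible to the
chain for a single frame (documented limitation).

## Three-step normalization

The published description names the three causes but not the formulas, so
the scheme here is this package's explicit contract, with each step
independently switchable:

1. divide each well's response by its illumination factor (ground-truth
   multiplier when known, else the well's recording-wide mean over the
   plate mean);
2. divide by the batch factor (batch mean of step-1 values over the grand
   mean);
3. subtract the well's mean step-2 value over the baseline window — the
   final 5 min of the in-recording pre-illumination epoch, the only
   adaptation period present in the data.

Degenerate factors (zero/non-finite) fall back to 1 with a warning and are
flagged in the report; the report inverts the transform exactly
(`unnormalize_activity`). Downstream inference uses group contrasts, which
are robust to the exact scheme: estimated factors are scale-free, so a
common rescaling of all wells passes through and preserves the sign and
ordering of contrasts.

## Assay statistics

**VMR.** Per larva, the burst duration within 1 s after each matching
transition, averaged across trials, then group mean ± SEM over larvae (n
counts larvae, matching the reporting convention). The 1 s window times the
per-bin burst duration is the assumed denominator of the published values.

**FSTR.** Burst duration in 30 s windows before/after each flash; the
percent response is `100 · post / pre` — the *post as percentage of pre*
reading, because the printed window means (0.0046 → 0.0082 s) reproduce
the printed 178% only under that reading. `pre = 0` yields an undefined
marker (`NA`), not an error. Forward and reverse presentations of a cue
length are averaged per larva before group statistics. A 1 s window
variant exists (`window_s = 1`); the two window conventions in the source
description are both supported and neither is declared canonical.

**Free swim.** Per-larva mean distance per 10 s bin and mean per-bin class
durations under constant illumination.

**Colour maze.** Per-arm mean count over timepoints and percent of the
group; supports the 4-colour and 2-colour + neutral variants.

## Ocular and morphometric metrics

`rre = 1 − retinal_radius / (2.324 · lens_radius)`; the factor 2.324 is
the idealized focal-length ratio used in OCT biometry of the fish eye
(`focal_length_factor`, an exposed constant). Positive RRE is hyperopic,
negative myopic. Per-fish metrics are computed first and then averaged
(`mean_of_fish`); the `ratio_of_means` variant — the metric evaluated on
cohort mean parameters — is exposed for arithmetic on published cohort
means. The two differ when parameters covary across fish, which is why the
published cohort RRE means (0.19/0.26) are not recoverable from the
published parameter means (0.147/0.211): that would require per-fish data.

The "head-to-midbrain ratio" is computed as `midbrain / head`: only that
orientation yields the published 0.74 (WT) and 0.69 (KO) from the
published trait means (0.52/0.70 and 0.52/0.75 mm). The label/formula
mismatch is deliberate and documented here. Triplicate morphometric
measurements are averaged per fish before reporting, with a warn-only 50%
replicate-CV check.

## Resampling statistics

**Bootstrap mean difference.** `mean(B) − mean(A)` with independent
with-replacement resampling of each group (default 5,000 resamples) and a
percentile 95% CI — the estimation-plot convention. BCa is out of scope.

**Rank-sum test.** Mid-rank statistic with three null models: exact
enumeration (combined n ≤ 12), random permutations with add-one smoothing
`(count + 1)/(n_perm + 1)` per tail, and a tie-corrected normal
approximation with continuity correction. Two-sided p-values double the
smaller tail (capped at 1); degenerate all-equal data gives p = 1.

**Relative expression.** The efficiency-corrected ratio
`E_t^ΔCt_t / geomean_r(E_r^ΔCt_r)` with `ΔCt = mean Ct(control) −
mean Ct(treated)` and the geometric mean over reference genes (the
standard multi-reference normalization). Significance comes from random
reallocation of group labels within each gene, recomputing the ratio
(default 2,000 randomizations) and scoring two-sided exceedance of
|log ratio| with add-one smoothing. The cited expression tool's exact
"pairwise fixed reallocation" scheme is not fully published; this
label-reallocation test is the stated contract.

## Numerical choices and problem sizes

* Frame interval 0.1 s by default — fine enough to render a 100 ms flash
  while keeping desk-scale simulation cheap; the state chain's one
  sequential loop is compiled code.
* Boundary comparisons on the bin grid use 1e-9 s guards; epoch contiguity
  is checked to the nearest millisecond.
* All simulators save and restore the caller's RNG state; every output is
  a pure function of its arguments including the seed.
* The property-test problem sizes are desk scale by design: 1,000 random
  traces for partition/conservation invariants, 96-well plates for
  normalization ground truth, 200 null replicates for p-value uniformity,
  and 100 replicate experiments (n = 24 per group, ten 1-min ON/OFF
  trials) for effect-recovery coverage. A single simulated qPCR table's
  ratio estimate has sampling SD ≈ fold · ln E · noise · √(2/9) · √(4/3)
  (≈ 0.057 at fold 1.5, noise 0.1, 9 replicates), so fold-recovery accuracy
  is assessed on the mean over 10 independent tables.

## Known limitations

* The normalization formulas are a reconstruction of a named three-step
  procedure, not a re-implementation of a published formula set.
* The simulator's coast-speed distribution does not depend on
  illumination, so one printed duration ordering is not reproduced (see
  above).
* Millisecond cues are rendered at single-frame resolution.
* Cohort RRE means that depend on per-fish covariance cannot be reproduced
  from cohort-mean inputs; both aggregations are exposed so the user can
  choose deliberately.
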