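#' Burst-glide locomotor model parameters
#'
#' Larval zebrafish swim in a burst-glide style: long stretches of slow
#' coasting (0-20 mm/s) and inactivity punctuated by short fast bursts
#' (>= 20 mm/s). The simulator models the latent activity state as a
#' discrete-time Markov chain with state-specific mean dwell times: at each
#' frame the chain leaves its state with probability
#' `frame_dt_s / dwell`, and on a switch draws the next state from the
#' illumination-conditional occupancy weights. A light transition transiently
#' multiplies the burst weight by `1 + gain * exp(-dt/startle_decay_s)`
#' (gain chosen by transition direction), emulating the startle response.
#'
#' The defaults are calibrated to wild-type (TL strain) larvae: free-swim
#' distances of roughly 34 mm per 10 s in light and 28 mm per 10 s in dark,
#' coast-dominant occupancy, a light-ON startle of about 0.16 s of burst in
#' the first second after the transition, and a light-OFF startle of about
#' 0.28 s. Note the target-state weights are occupancies at switch times,
#' not stationary shares: the chain's stationary distribution is
#' proportional to weight times dwell.
#'
#' @param occupancy 3 x 2 matrix of baseline state-occupancy probabilities
#'   (rows inactive/coast/burst, columns light/dark), each column summing
#'   to 1.
#' @param dwell_s 3 x 2 matrix of mean state dwell times in seconds (same
#'   layout).
#' @param coast_speed shape parameters `c(a, b)` of a Beta distribution
#'   scaled to (0, 20) mm/s.
#' @param burst_speed shape and scale `c(shape, scale)` of the Gamma excess
#'   over 20 mm/s.
#' @param startle_gain_on,startle_gain_off dimensionless burst-weight gains
#'   applied after ON / OFF transitions (>= 0).
#' @param startle_decay_s exponential decay constant of the startle kernel.
#' @param frame_dt_s simulation step in seconds.
#' @param activity_scale multiplicative speed scaling (nuisance factor used
#'   by [simulate_plate()]).
#' @return object of class `locomotor_params`.
#' @export
locomotor_params <- function(
    occupancy = cbind(light = c(0.567, 0.417, 0.016),
                      dark = c(0.689, 0.304, 0.007)),
    dwell_s = cbind(light = c(0.8, 1.2, 0.3),
                    dark = c(0.8, 1.5, 0.3)),
    coast_speed = c(2, 4.5),
    burst_speed = c(2, 7.5),
    startle_gain_on = 92,
    startle_gain_off = 700,
    startle_decay_s = 1,
    frame_dt_s = 0.1,
    activity_scale = 1) {
  occupancy <- as.matrix(occupancy)
  dwell_s <- as.matrix(dwell_s)
  rownames(occupancy) <- rownames(dwell_s) <- c("inactive", "coast", "burst")
  if (any(occupancy < 0) || any(occupancy > 1) ||
      any(abs(colSums(occupancy) - 1) > 1e-9)) {
    stop("occupancy columns must be probabilities summing to 1", call. = FALSE)
  }
  if (any(dwell_s <= 0)) stop("dwell times must be > 0", call. = FALSE)
  if (any(c(coast_speed, burst_speed) <= 0)) {
    stop("speed distribution parameters must be > 0", call. = FALSE)
  }
  if (startle_gain_on < 0 || startle_gain_off < 0) {
    stop("startle gains must be >= 0", call. = FALSE)
  }
  if (frame_dt_s <= 0) stop("frame_dt_s must be > 0", call. = FALSE)
  if (activity_scale <= 0) stop("activity_scale must be > 0", call. = FALSE)
  structure(
    list(occupancy = occupancy, dwell_s = dwell_s,
         coast_speed = coast_speed, burst_speed = burst_speed,
         startle_gain_on = startle_gain_on,
         startle_gain_off = startle_gain_off,
         startle_decay_s = startle_decay_s,
         frame_dt_s = frame_dt_s, activity_scale = activity_scale),
    class = "locomotor_params"
  )
}

#' Genotype configuration for the simulator
#'
#' Bundles a label, locomotor parameter overrides, and biometry cohort
#' moments. The default knock-out calibration encodes the observed effect
#' directions: a 12.5% larger light-ON startle gain, a 21% shorter dark
#' coast dwell, and a 5% smaller mesopic startle gain, all relative to
#' wild type.
#'
#' @param label genotype name, e.g. `"WT"` or `"KO"`.
#' @param params a `locomotor_params`.
#' @param biometry_means,biometry_sds named numeric vectors of per-fish
#'   biometry moments; names among `body_length_mm`, `axial_length_um`,
#'   `lens_diam_pd_um`, `lens_diam_ap_um`, `lens_radius_um`,
#'   `retinal_radius_um`, `retinal_thickness_um`.
#' @param biometry_corr correlation between lens radius and retinal radius,
#'   in \[-1, 1\].
#' @return object of class `genotype_config`.
#' @export
genotype_config <- function(label, params = locomotor_params(),
                            biometry_means = NULL, biometry_sds = NULL,
                            biometry_corr = 0.5) {
  stopifnot(inherits(params, "locomotor_params"))
  if (abs(biometry_corr) > 1) stop("|biometry_corr| must be <= 1", call. = FALSE)
  if (!is.null(biometry_sds) && any(biometry_sds < 0)) {
    stop("biometry SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(label = label, params = params,
         biometry_means = biometry_means, biometry_sds = biometry_sds,
         biometry_corr = biometry_corr),
    class = "genotype_config"
  )
}

#' Default wild-type and knock-out genotype configurations
#'
#' `wt_genotype()` uses the baseline locomotor parameters and the TL cohort
#' biometry moments; `ko_genotype()` applies the knock-out calibration
#' (light-ON startle gain x1.125, dark coast dwell x0.79, and for the
#' mesopic variant a startle gain x0.95) plus the knock-out biometry
#' moments.
#'
#' @param mesopic if `TRUE` the knock-out's ON gain is scaled by 0.95
#'   instead of 1.125 (rod-mediated reversal at 5% light).
#' @return a `genotype_config`.
#' @export
wt_genotype <- function() {
  genotype_config(
    "WT",
    locomotor_params(),
    biometry_means = c(body_length_mm = 24.33, axial_length_um = 217.0,
                       lens_diam_pd_um = 728, lens_diam_ap_um = 720,
                       lens_radius_um = 362.12, retinal_radius_um = 717.52,
                       retinal_thickness_um = 196.07),
    biometry_sds = c(body_length_mm = 1.84, axial_length_um = 21.0,
                     lens_diam_pd_um = 41, lens_diam_ap_um = 41,
                     lens_radius_um = 20.50, retinal_radius_um = 66.23,
                     retinal_thickness_um = 15.17),
    biometry_corr = 0.5
  )
}

#' @rdname wt_genotype
#' @export
ko_genotype <- function(mesopic = FALSE) {
  p <- locomotor_params()
  p$startle_gain_on <- p$startle_gain_on * (if (mesopic) 0.95 else 1.125)
  p$dwell_s["coast", "dark"] <- p$dwell_s["coast", "dark"] * 0.79
  genotype_config(
    "KO",
    p,
    biometry_means = c(body_length_mm = 24.94, axial_length_um = 198.8,
                       lens_diam_pd_um = 709, lens_diam_ap_um = 695,
                       lens_radius_um = 351.15, retinal_radius_um = 643.52,
                       retinal_thickness_um = 204.16),
    biometry_sds = c(body_length_mm = 1.52, axial_length_um = 12.5,
                     lens_diam_pd_um = 36, lens_diam_ap_um = 36,
                     lens_radius_um = 17.99, retinal_radius_um = 78.40,
                     retinal_thickness_um = 25.36),
    biometry_corr = 0.5
  )
}

#' Plate layout and nuisance-variation specification
#'
#' @param n_wells wells per plate, 48 or 96.
#' @param well_light_sd relative SD of the per-well received-light
#'   (activity) multiplier.
#' @param batch_ids character vector of experimental batch labels.
#' @param batch_effect_sd relative SD of the per-batch activity multiplier.
#' @return object of class `plate_spec`.
#' @export
plate_spec <- function(n_wells = 48, well_light_sd = 0.1,
                       batch_ids = c("b1", "b2"), batch_effect_sd = 0.2) {
  if (!n_wells %in% c(48L, 96L)) stop("n_wells must be 48 or 96", call. = FALSE)
  if (well_light_sd < 0 || batch_effect_sd < 0) {
    stop("SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(n_wells = n_wells, well_light_sd = well_light_sd,
         batch_ids = as.character(batch_ids),
         batch_effect_sd = batch_effect_sd),
    class = "plate_spec"
  )
}

# per-frame startle multiplier on the burst occupancy weight: the most
# recent transition's kernel (inter-transition gaps are long relative to
# the decay constant, so kernels effectively never overlap)
.burst_multiplier <- function(protocol, params, n_frames) {
  dt <- params$frame_dt_s
  t_frames <- (seq_len(n_frames) - 1) * dt
  mult <- rep(1, n_frames)
  tr <- transitions(protocol)
  if (nrow(tr) == 0L) return(mult)
  idx <- findInterval(t_frames + 1e-9, tr$time_s)
  has <- idx >= 1
  gain <- ifelse(tr$direction == "ON", params$startle_gain_on,
                 params$startle_gain_off)
  dtt <- t_frames[has] - tr$time_s[idx[has]]
  mult[has] <- 1 + gain[idx[has]] * exp(-dtt / params$startle_decay_s)
  mult
}

#' Simulate one swim-speed trace
#'
#' Evolves the three-state burst-glide Markov chain over the protocol's
#' illumination schedule and draws per-frame speeds from the current state's
#' distribution (0 for inactive, scaled Beta on (0, 20) mm/s for coast,
#' 20 mm/s plus a Gamma excess for burst). Output is a pure function of
#' `(protocol, params, seed)`.
#'
#' @param protocol an `assay_protocol`.
#' @param params a `locomotor_params`; `frame_dt_s` must divide the
#'   protocol's `bin_s`.
#' @param seed integer seed.
#' @param well_id,genotype,batch metadata for the resulting trace.
#' @return a `speed_trace`.
#' @export
simulate_trace <- function(protocol, params, seed, well_id = "w01",
                           genotype = "WT", batch = "b1") {
  stopifnot(inherits(protocol, "assay_protocol"),
            inherits(params, "locomotor_params"))
  dt <- params$frame_dt_s
  if (abs(protocol$bin_s / dt - round(protocol$bin_s / dt)) > 1e-9) {
    stop("frame_dt_s must divide the protocol bin_s", call. = FALSE)
  }
  intensity <- protocol_intensity(protocol, dt)
  n <- length(intensity)
  illum_dark <- as.integer(intensity <= 0)
  bmult <- .burst_multiplier(protocol, params, n)

  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  init <- sample.int(3L, 1L, prob = params$occupancy[, illum_dark[1] + 1L])
  states <- .state_chain(n, dt, params$occupancy, params$dwell_s,
                         illum_dark, bmult, init)
  v <- numeric(n)
  ic <- states == 2L
  ib <- states == 3L
  v[ic] <- 20 * stats::rbeta(sum(ic), params$coast_speed[1],
                             params$coast_speed[2])
  v[ib] <- 20 + stats::rgamma(sum(ib), shape = params$burst_speed[1],
                              scale = params$burst_speed[2])
  v <- v * params$activity_scale
  speed_trace(well_id, genotype, batch, dt, v)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a full plate experiment
#'
#' Assigns each larva a well, batch, and genotype, draws the per-well
#' illumination multiplier and per-batch activity multiplier once (recorded
#' as ground truth in the metadata), and simulates every trace. Multipliers
#' act multiplicatively on swim speed.
#'
#' @param protocol an `assay_protocol`.
#' @param genotypes list of `genotype_config`.
#' @param n_per_genotype larvae per genotype.
#' @param plate a `plate_spec`. Capacity is
#'   `n_wells * length(batch_ids)`.
#' @param seed integer seed.
#' @return list with elements `traces` (list of `speed_trace`) and
#'   `metadata` (tibble with `well_id`, `genotype`, `batch`, `well_mult`,
#'   `batch_mult`).
#' @export
simulate_plate <- function(protocol, genotypes, n_per_genotype, plate, seed) {
  stopifnot(inherits(plate, "plate_spec"))
  n_total <- n_per_genotype * length(genotypes)
  capacity <- plate$n_wells * length(plate$batch_ids)
  if (n_total > capacity) {
    stop("capacity exceeded: ", n_total, " larvae > ", capacity, " wells",
         call. = FALSE)
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)

  batch <- rep(plate$batch_ids, each = plate$n_wells)[seq_len(n_total)]
  well_in_plate <- ((seq_len(n_total) - 1) %% plate$n_wells) + 1
  well_id <- sprintf("%s_w%02d", batch, well_in_plate)
  geno <- rep(vapply(genotypes, function(g) g$label, character(1)),
              each = n_per_genotype)
  # randomize genotype placement across wells
  geno <- sample(geno)

  well_mult <- if (plate$well_light_sd > 0) {
    stats::rlnorm(n_total, meanlog = -plate$well_light_sd^2 / 2,
                  sdlog = plate$well_light_sd)
  } else rep(1, n_total)
  bm <- if (plate$batch_effect_sd > 0) {
    stats::rlnorm(length(plate$batch_ids),
                  meanlog = -plate$batch_effect_sd^2 / 2,
                  sdlog = plate$batch_effect_sd)
  } else rep(1, length(plate$batch_ids))
  batch_mult <- bm[match(batch, plate$batch_ids)]

  gmap <- stats::setNames(genotypes,
                          vapply(genotypes, function(g) g$label, character(1)))
  trace_seeds <- sample.int(.Machine$integer.max %/% 2L, n_total)
  traces <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- gmap[[geno[i]]]$params
    p$activity_scale <- p$activity_scale * well_mult[i] * batch_mult[i]
    traces[[i]] <- simulate_trace(protocol, p, trace_seeds[i],
                                  well_id = well_id[i], genotype = geno[i],
                                  batch = batch[i])
  }
  list(
    traces = traces,
    metadata = tibble::tibble(well_id = well_id, genotype = geno,
                              batch = batch, well_mult = well_mult,
                              batch_mult = batch_mult)
  )
}

#' Simulate an ocular biometry table
#'
#' Per-fish correlated Gaussian draws (truncated at zero) of body length,
#' axial length, the two lens diameters, lens radius, retinal radius, and
#' retinal thickness. The lens radius and retinal radius share the
#' genotype's `biometry_corr`; all other traits are independent.
#'
#' @param n fish per cohort (>= 2).
#' @param genotype a `genotype_config` with biometry moments.
#' @param seed integer seed.
#' @return tibble, one row per fish.
#' @export
simulate_biometry <- function(n, genotype, seed) {
  stopifnot(inherits(genotype, "genotype_config"), n >= 2)
  mu <- genotype$biometry_means
  sd <- genotype$biometry_sds
  if (is.null(mu) || is.null(sd)) {
    stop("genotype has no biometry moments", call. = FALSE)
  }
  rho <- genotype$biometry_corr
  if (abs(rho) >= 1 - 1e-12 && rho != 0) {
    # still positive semi-definite at |rho| = 1; reject beyond
    if (abs(rho) > 1) stop("correlation not positive definite", call. = FALSE)
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)

  draw <- function(trait) {
    pmax(stats::rnorm(n, mu[[trait]], sd[[trait]]), 0)
  }
  # correlated pair: lens radius & retinal radius via Cholesky
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  lens <- pmax(mu[["lens_radius_um"]] + sd[["lens_radius_um"]] * z1, 0)
  retina <- pmax(mu[["retinal_radius_um"]] + sd[["retinal_radius_um"]] * z2, 0)
  # diameters track the drawn radius (radius ~ mean diameter / 2 per fish)
  # plus a small independent residual that carries lens-ratio variability;
  # residual scales with the trait SD so zero-SD cohorts stay degenerate
  diam <- function(trait) {
    pmax(lens * mu[[trait]] / mu[["lens_radius_um"]] +
           stats::rnorm(n, 0, 0.17 * sd[[trait]]), 0)
  }

  tibble::tibble(
    fish_id = sprintf("%s_f%03d", genotype$label, seq_len(n)),
    genotype = genotype$label,
    body_length_mm = draw("body_length_mm"),
    axial_length_um = draw("axial_length_um"),
    lens_diam_pd_um = diam("lens_diam_pd_um"),
    lens_diam_ap_um = diam("lens_diam_ap_um"),
    lens_radius_um = lens,
    retinal_radius_um = retina,
    retinal_thickness_um = draw("retinal_thickness_um")
  )
}

#' Simulate a triplicate morphometry table
#'
#' Each fish has true body length, head length, and midbrain diameter drawn
#' from the cohort moments; three replicate measurements per trait add
#' independent Gaussian measurement noise.
#'
#' @param n fish per cohort.
#' @param means,sds named numeric vectors with names `body_mm`, `head_mm`,
#'   `midbrain_mm` (cohort-level mean and between-fish SD per trait).
#' @param replicate_sd SD of within-fish replicate measurement noise (mm).
#' @param seed integer seed.
#' @param label genotype label.
#' @return tibble with columns `fish_id`, `genotype`, and
#'   `<trait>_1 .. <trait>_3` for each trait.
#' @export
simulate_morphometry <- function(n, means, sds, replicate_sd = 0.02, seed,
                                 label = "WT") {
  if (replicate_sd < 0) stop("replicate_sd must be >= 0", call. = FALSE)
  traits <- c("body_mm", "head_mm", "midbrain_mm")
  stopifnot(all(traits %in% names(means)), all(traits %in% names(sds)))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  out <- tibble::tibble(
    fish_id = sprintf("%s_f%03d", label, seq_len(n)),
    genotype = label
  )
  for (tr in traits) {
    true <- pmax(stats::rnorm(n, means[[tr]], sds[[tr]]), 1e-6)
    for (r in 1:3) {
      out[[paste0(tr, "_", r)]] <-
        pmax(true + stats::rnorm(n, 0, replicate_sd), 1e-6)
    }
  }
  out
}

#' Simulate a qPCR Ct table
#'
#' Control-group quantification cycles are drawn around gene-specific
#' baselines; treated-group cycles are shifted by `-log_E(fold_change)`
#' so that the efficiency-corrected ratio recovers the specified fold
#' change. Reference genes must be given fold change 1.
#'
#' @param genes character vector of gene names.
#' @param fold_changes named numeric vector of treated/control expression
#'   ratios (> 0), one per gene.
#' @param efficiencies named numeric vector of amplification efficiencies E
#'   (fold per cycle, 1 < E <= 2.1), one per gene.
#' @param reference_genes genes used for normalization (fold change 1).
#' @param n_reps replicates per gene x group.
#' @param ct_noise_sd per-replicate Ct noise SD (cycles).
#' @param baseline_ct named vector of control-group baseline Cts (defaults
#'   to 20 for every gene).
#' @param seed integer seed.
#' @return tibble with columns `gene`, `role`, `group`, `replicate`, `ct`,
#'   `efficiency`.
#' @export
simulate_ct_table <- function(genes, fold_changes, efficiencies,
                              reference_genes, n_reps = 3, ct_noise_sd = 0.1,
                              baseline_ct = NULL, seed = 1) {
  stopifnot(all(genes %in% names(fold_changes)),
            all(genes %in% names(efficiencies)))
  if (any(fold_changes <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (any(efficiencies <= 1)) stop("efficiencies must be > 1", call. = FALSE)
  if (any(abs(fold_changes[reference_genes] - 1) > 1e-12)) {
    stop("reference genes must have fold change 1", call. = FALSE)
  }
  if (is.null(baseline_ct)) {
    baseline_ct <- stats::setNames(rep(20, length(genes)), genes)
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  rows <- lapply(genes, function(g) {
    shift <- -log(fold_changes[[g]]) / log(efficiencies[[g]])
    ct_c <- baseline_ct[[g]] + stats::rnorm(n_reps, 0, ct_noise_sd)
    ct_t <- baseline_ct[[g]] + shift + stats::rnorm(n_reps, 0, ct_noise_sd)
    tibble::tibble(
      gene = g,
      role = if (g %in% reference_genes) "reference" else "target",
      group = rep(c("control", "treated"), each = n_reps),
      replicate = rep(seq_len(n_reps), 2),
      ct = c(ct_c, ct_t),
      efficiency = efficiencies[[g]]
    )
  })
  do.call(rbind, rows)
}

#' Simulate colour-maze count tables
#'
#' At each observation timepoint the positions of `n_fish` larvae across the
#' maze arms are drawn from a multinomial with the normalized preference
#' weights; counts sum to `n_fish` at every timepoint.
#'
#' @param n_fish number of larvae (<= 20).
#' @param arm_weights named non-negative preference weights (not all zero);
#'   names become the arm columns.
#' @param n_timepoints number of count observations (one every 2 min in the
#'   assay).
#' @param seed integer seed.
#' @return tibble with a `timepoint` column plus one count column per arm.
#' @export
simulate_color_maze <- function(n_fish, arm_weights, n_timepoints, seed) {
  if (n_fish > 20) stop("at most 20 larvae per maze run", call. = FALSE)
  if (any(arm_weights < 0) || sum(arm_weights) <= 0) {
    stop("arm weights must be >= 0 and not all zero", call. = FALSE)
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  pr <- arm_weights / sum(arm_weights)
  counts <- t(stats::rmultinom(n_timepoints, n_fish, pr))
  out <- tibble::as_tibble(as.data.frame(counts))
  names(out) <- names(arm_weights)
  tibble::tibble(timepoint = seq_len(n_timepoints), out)
}
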