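#' Classify swim speeds into activity classes
#'
#' Larval zebrafish locomotion is categorized into three activity classes by
#' instantaneous swim speed: inactive (0 mm/s), coast swimming (between 0 and
#' 20 mm/s), and burst swimming (at or above 20 mm/s). The 20 mm/s boundary
#' is assigned to burst so the burst class is closed; both the threshold and
#' its inclusivity are arguments.
#'
#' @param v numeric vector of speeds in mm/s; must be finite and >= 0.
#' @param coast_max_mm_s burst threshold, default 20.
#' @param burst_inclusive if `TRUE` (default) a speed equal to the threshold
#'   is burst; if `FALSE` it is coast.
#' @return factor with levels `inactive`, `coast`, `burst`.
#' @export
classify_speed <- function(v, coast_max_mm_s = 20, burst_inclusive = TRUE) {
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("speeds must be finite and non-negative", call. = FALSE)
  }
  cls <- ifelse(v == 0, "inactive",
                ifelse(if (burst_inclusive) v >= coast_max_mm_s
                       else v > coast_max_mm_s,
                       "burst", "coast"))
  factor(cls, levels = c("inactive", "coast", "burst"))
}

#' Segment a speed trace into bouts
#'
#' A bout is a maximal run of consecutive frames sharing one activity class.
#' Bout durations partition the trace exactly and bout distances sum to the
#' trace's total distance (speed times frame interval, summed).
#'
#' @param trace a `speed_trace` (see [speed_trace()]).
#' @inheritParams classify_speed
#' @return tibble with columns `activity_class`, `start_s`, `duration_s`,
#'   `distance_mm`.
#' @export
segment_bouts <- function(trace, coast_max_mm_s = 20, burst_inclusive = TRUE) {
  stopifnot(inherits(trace, "speed_trace"))
  v <- trace$speeds
  dt <- trace$frame_dt_s
  cls <- classify_speed(v, coast_max_mm_s, burst_inclusive)
  r <- rle(as.integer(cls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cs <- cumsum(v)
  dist <- (cs[ends] - c(0, cs[ends[-length(ends)]])) * dt
  tibble::tibble(
    activity_class = factor(levels(cls)[r$values],
                            levels = levels(cls)),
    start_s = (starts - 1) * dt,
    duration_s = r$lengths * dt,
    distance_mm = dist
  )
}

#' Aggregate a speed trace into binned activity records
#'
#' Produces one record per acquisition bin with per-class durations
#' (frames in class times the frame interval), per-class distances, and
#' bout counts. A bout is counted in the bin containing its first frame.
#'
#' @param trace a `speed_trace`.
#' @param bin_s bin length in seconds; must be a multiple of the frame
#'   interval and divide the trace duration.
#' @inheritParams classify_speed
#' @return tibble of binned activity records (see [write_records()] for the
#'   column contract).
#' @export
bin_activity <- function(trace, bin_s, coast_max_mm_s = 20,
                         burst_inclusive = TRUE) {
  stopifnot(inherits(trace, "speed_trace"))
  dt <- trace$frame_dt_s
  fpb <- bin_s / dt
  if (abs(fpb - round(fpb)) > 1e-9) {
    stop("frame interval must divide `bin_s`", call. = FALSE)
  }
  fpb <- round(fpb)
  n <- length(trace$speeds)
  if (n %% fpb != 0) {
    stop("`bin_s` must divide the trace duration", call. = FALSE)
  }
  n_bins <- n %/% fpb
  bin_idx <- rep(seq_len(n_bins), each = fpb)
  v <- trace$speeds
  cls <- classify_speed(v, coast_max_mm_s, burst_inclusive)

  dur <- function(which) {
    tab <- tapply(cls == which, bin_idx, sum)
    as.numeric(tab) * dt
  }
  dist <- function(which) {
    tab <- tapply(v * (cls == which), bin_idx, sum)
    as.numeric(tab) * dt
  }
  bouts <- segment_bouts(trace, coast_max_mm_s, burst_inclusive)
  count_bouts <- function(which) {
    b <- bouts[bouts$activity_class == which, ]
    start_bin <- floor(b$start_s / bin_s + 1e-9) + 1
    as.numeric(tabulate(start_bin, nbins = n_bins))
  }

  tibble::tibble(
    well_id = trace$well_id,
    genotype = trace$genotype,
    batch = trace$batch,
    bin_start_s = (seq_len(n_bins) - 1) * bin_s,
    bin_s = bin_s,
    dur_inactive_s = dur("inactive"),
    dur_coast_s = dur("coast"),
    dur_burst_s = dur("burst"),
    dist_coast_mm = dist("coast"),
    dist_burst_mm = dist("burst"),
    n_bouts_coast = count_bouts("coast"),
    n_bouts_burst = count_bouts("burst")
  )
}
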