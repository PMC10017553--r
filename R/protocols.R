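#' Assay illumination protocols
#'
#' An `assay_protocol` describes the illumination schedule of a plate-based
#' behavioural recording as an ordered, contiguous sequence of light epochs.
#' Time zero is the start of the recording; any dark/light adaptation that
#' happens before the recording starts is carried as metadata
#' (`adaptation_s`) and contributes no epochs.
#'
#' Intensities are percent of the enclosure maximum (100% corresponds to a
#' nominal 8,000 lux); only relative percent matters downstream.
#'
#' @param name protocol label, e.g. `"vmr"` or `"fstr"`.
#' @param epochs a data frame with columns `start_s`, `duration_s`,
#'   `intensity_pct`. Epochs must be contiguous (each `start_s` equals the
#'   previous epoch's end) and start at 0.
#' @param bin_s acquisition bin length in seconds; one of 1, 10, 60, 300.
#' @param adaptation_s seconds of pre-recording adaptation (metadata only).
#' @param adaptation_pct illumination during the adaptation period, percent.
#'   When it differs from the first epoch's intensity, the recording opens
#'   with a light transition at t = 0 (e.g. a dark-adapted larva whose first
#'   epoch is lit). Defaults to the first epoch's intensity (no t = 0
#'   transition).
#' @param strict_bins if `TRUE` (default), every epoch boundary must land on
#'   the `bin_s` grid. Flash protocols with millisecond cues set this to
#'   `FALSE`: sub-bin epochs cannot align and their analysis windows are
#'   anchored on transitions, not bin edges.
#' @return an object of class `assay_protocol`.
#' @export
assay_protocol <- function(name, epochs, bin_s, adaptation_s = 0,
                           adaptation_pct = NULL, strict_bins = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!bin_s %in% c(1, 10, 60, 300)) {
    stop("`bin_s` must be one of 1, 10, 60, 300 seconds", call. = FALSE)
  }
  epochs <- tibble::as_tibble(epochs)
  req <- c("start_s", "duration_s", "intensity_pct")
  if (!all(req %in% names(epochs))) {
    stop("`epochs` needs columns start_s, duration_s, intensity_pct",
         call. = FALSE)
  }
  if (nrow(epochs) == 0L) stop("protocol needs at least one epoch", call. = FALSE)
  if (any(epochs$duration_s <= 0)) {
    stop("epoch durations must be > 0", call. = FALSE)
  }
  if (any(epochs$intensity_pct < 0 | epochs$intensity_pct > 100)) {
    stop("intensities must lie in [0, 100] percent", call. = FALSE)
  }
  # contiguity to the nearest millisecond
  ends <- epochs$start_s + epochs$duration_s
  expected_starts <- c(0, ends[-length(ends)])
  if (any(abs(epochs$start_s - expected_starts) > 1e-3)) {
    stop("epochs must be contiguous and start at t = 0", call. = FALSE)
  }
  if (strict_bins) {
    bounds <- c(epochs$start_s, ends[length(ends)])
    off <- abs(bounds / bin_s - round(bounds / bin_s))
    if (any(off > 1e-9)) {
      stop("schedule-alignment error: epoch boundaries must land on the ",
           bin_s, " s bin grid", call. = FALSE)
    }
  }
  if (is.null(adaptation_pct)) adaptation_pct <- epochs$intensity_pct[1]
  structure(
    list(name = name, adaptation_s = adaptation_s,
         adaptation_pct = adaptation_pct, bin_s = bin_s,
         epochs = epochs, strict_bins = strict_bins),
    class = "assay_protocol"
  )
}

#' @export
print.assay_protocol <- function(x, ...) {
  cat(sprintf("<assay_protocol> %s: %d epochs, %.1f s total, bin %g s\n",
              x$name, nrow(x$epochs), protocol_duration(x), x$bin_s))
  print(x$epochs, n = 10)
  invisible(x)
}

#' Total recorded duration of a protocol in seconds
#' @param protocol an `assay_protocol`.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "assay_protocol"))
  sum(protocol$epochs$duration_s)
}

#' Build a VMR (visual motor response) protocol
#'
#' A pre-illumination dark period followed by `n_trials` cycles of 30 min
#' light-ON / 30 min light-OFF. The standard assay uses 3 trials with a
#' 30 min pre-dark period (3.5 h tracked); the mesopic variant uses 2 trials
#' at 5% light-ON intensity (2.5 h tracked).
#'
#' @param n_trials number of ON/OFF cycles, 2 or 3.
#' @param on_intensity_pct light-ON intensity in percent (30 standard,
#'   5 mesopic).
#' @param pre_dark_min minutes of in-recording darkness before the first
#'   ON transition.
#' @param bin_s acquisition bin length (seconds).
#' @return an `assay_protocol`.
#' @export
make_vmr_protocol <- function(n_trials = 3, on_intensity_pct = 30,
                              pre_dark_min = 30, bin_s = 1) {
  if (!n_trials %in% c(2L, 3L)) stop("`n_trials` must be 2 or 3", call. = FALSE)
  if (pre_dark_min < 0) stop("`pre_dark_min` must be >= 0", call. = FALSE)
  durs <- c(if (pre_dark_min > 0) pre_dark_min * 60,
            rep(c(1800, 1800), n_trials))
  ints <- c(if (pre_dark_min > 0) 0,
            rep(c(on_intensity_pct, 0), n_trials))
  starts <- cumsum(c(0, durs[-length(durs)]))
  name <- if (on_intensity_pct <= 5) "vmr_mesopic" else "vmr"
  assay_protocol(
    name,
    tibble::tibble(start_s = starts, duration_s = durs, intensity_pct = ints),
    bin_s = bin_s,
    adaptation_s = 2 * 3600,
    adaptation_pct = 0
  )
}

#' Build an FSTR (flash stimulus threshold response) protocol
#'
#' Alternates a brief light cue at 30% intensity with a dark rest period.
#' Cue lengths are given in milliseconds; the standard series is
#' 10, 20, 50, 100, 250, 500, 1000 ms, presented in forward and in reverse
#' order across runs to cancel habituation.
#'
#' @param cue_lengths_ms flash durations in milliseconds.
#' @param rest_min dark rest between cues, minutes.
#' @param order `"forward"` or `"reverse"` presentation order.
#' @param bin_s acquisition bin length (seconds).
#' @param frame_dt_s smallest renderable time step; cues shorter than this
#'   are rejected.
#' @param flash_intensity_pct flash intensity, percent.
#' @param pre_dark_min minutes of recorded darkness before the first cue
#'   (0 puts the first flash at t = 0; a positive value leaves room for
#'   pre-stimulus analysis windows and baseline normalization).
#' @return an `assay_protocol` (with relaxed bin alignment: millisecond cues
#'   cannot land on the bin grid).
#' @export
make_fstr_protocol <- function(cue_lengths_ms, rest_min = 20,
                               order = c("forward", "reverse"), bin_s = 1,
                               frame_dt_s = 0.01, flash_intensity_pct = 30,
                               pre_dark_min = 0) {
  order <- match.arg(order)
  if (length(cue_lengths_ms) < 1L || any(cue_lengths_ms <= 0)) {
    stop("cue lengths must be positive", call. = FALSE)
  }
  if (rest_min <= 0) stop("`rest_min` must be > 0", call. = FALSE)
  if (any(cue_lengths_ms / 1000 < frame_dt_s - 1e-12)) {
    stop("cue shorter than the trace frame interval (", frame_dt_s,
         " s) cannot be rendered", call. = FALSE)
  }
  cues <- if (order == "reverse") rev(cue_lengths_ms) else cue_lengths_ms
  durs <- as.numeric(rbind(cues / 1000, rest_min * 60))
  ints <- as.numeric(rbind(rep(flash_intensity_pct, length(cues)),
                           rep(0, length(cues))))
  if (pre_dark_min > 0) {
    durs <- c(pre_dark_min * 60, durs)
    ints <- c(0, ints)
  }
  starts <- cumsum(c(0, durs[-length(durs)]))
  assay_protocol(
    "fstr",
    tibble::tibble(start_s = starts, duration_s = durs, intensity_pct = ints),
    bin_s = bin_s,
    adaptation_s = 2 * 3600,
    adaptation_pct = 0,
    strict_bins = FALSE
  )
}

#' Build a constant-illumination free-swim protocol
#'
#' @param duration_min recording length in minutes.
#' @param intensity_pct constant intensity (30 for light, 0 for dark).
#' @param bin_s acquisition bin length (seconds).
#' @return an `assay_protocol`.
#' @export
make_freeswim_protocol <- function(duration_min = 5, intensity_pct = 30,
                                   bin_s = 10) {
  name <- if (intensity_pct > 0) "freeswim_light" else "freeswim_dark"
  assay_protocol(
    name,
    tibble::tibble(start_s = 0, duration_s = duration_min * 60,
                   intensity_pct = intensity_pct),
    bin_s = bin_s,
    adaptation_s = 2 * 3600
  )
}

#' Light transitions of a protocol
#'
#' One row per adjacent epoch pair with unequal intensity, plus a t = 0
#' transition when the first epoch's intensity differs from the adaptation
#' illumination (a dark-adapted larva meeting a lit first epoch). A
#' transition is `ON` when intensity increases and `OFF` when it decreases;
#' these anchor the VMR and FSTR response windows.
#'
#' @param protocol an `assay_protocol`.
#' @return a tibble with columns `time_s`, `direction`, `from_pct`, `to_pct`,
#'   sorted by time.
#' @export
transitions <- function(protocol) {
  stopifnot(inherits(protocol, "assay_protocol"))
  ep <- protocol$epochs
  n <- nrow(ep)
  from <- c(protocol$adaptation_pct, ep$intensity_pct[-n])
  to <- ep$intensity_pct
  keep <- from != to
  tibble::tibble(
    time_s = ep$start_s[keep],
    direction = ifelse(to[keep] > from[keep], "ON", "OFF"),
    from_pct = from[keep],
    to_pct = to[keep]
  )
}

#' Per-frame illumination of a protocol
#'
#' Intensity sampled at frame start times on a regular grid. Sub-frame
#' epochs (millisecond flashes) are rendered by at least one frame sample:
#' any frame whose interval overlaps a brighter epoch takes that epoch's
#' intensity, so a 10 ms flash is visible at `frame_dt_s = 0.1`.
#'
#' @param protocol an `assay_protocol`.
#' @param frame_dt_s frame interval in seconds.
#' @return numeric vector of intensity percent, one per frame.
#' @export
protocol_intensity <- function(protocol, frame_dt_s) {
  stopifnot(inherits(protocol, "assay_protocol"), frame_dt_s > 0)
  total <- protocol_duration(protocol)
  n <- round(total / frame_dt_s)
  t0 <- (seq_len(n) - 1) * frame_dt_s
  ep <- protocol$epochs
  idx <- findInterval(t0 + 1e-9, ep$start_s)
  out <- ep$intensity_pct[idx]
  # render sub-frame epochs: a brighter epoch overlapping the frame wins
  sub <- which(ep$duration_s < frame_dt_s)
  for (k in sub) {
    f <- floor(ep$start_s[k] / frame_dt_s) + 1
    if (f >= 1 && f <= n && ep$intensity_pct[k] > out[f]) {
      out[f] <- ep$intensity_pct[k]
    }
  }
  out
}

#' Write / read a protocol as YAML
#'
#' The document stores `name`, `adaptation_s`, `bin_s`, `strict_bins`, and
#' `epochs` as a list of `[start_s, duration_s, intensity_pct]` triples.
#'
#' @param protocol an `assay_protocol`.
#' @param path file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns an `assay_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "assay_protocol"))
  doc <- list(
    name = protocol$name,
    adaptation_s = protocol$adaptation_s,
    adaptation_pct = protocol$adaptation_pct,
    bin_s = protocol$bin_s,
    strict_bins = protocol$strict_bins,
    epochs = lapply(seq_len(nrow(protocol$epochs)), function(i) {
      as.numeric(protocol$epochs[i, c("start_s", "duration_s",
                                      "intensity_pct")])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  ep <- do.call(rbind, lapply(doc$epochs, as.numeric))
  assay_protocol(
    doc$name,
    tibble::tibble(start_s = ep[, 1], duration_s = ep[, 2],
                   intensity_pct = ep[, 3]),
    bin_s = doc$bin_s,
    adaptation_s = doc$adaptation_s,
    adaptation_pct = doc$adaptation_pct,
    strict_bins = isTRUE(doc$strict_bins)
  )
}
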