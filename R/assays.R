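#' Group response summary
#'
#' All assay statistics are reported per larva first, then summarized per
#' genotype group as mean +/- SEM over larvae.
#'
#' @param per_larva tibble with columns `well_id`, `genotype`, `value`.
#' @param assay assay label.
#' @return object of class `response_summary`: list with `assay`,
#'   `per_larva`, and `summary` (tibble `genotype`, `mean`, `sem`, `n`).
#' @export
response_summary <- function(per_larva, assay) {
  g <- split(per_larva$value, per_larva$genotype)
  smry <- tibble::tibble(
    genotype = names(g),
    mean = unname(vapply(g, mean, numeric(1))),
    sem = unname(vapply(g, function(v) {
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, numeric(1))),
    n = unname(vapply(g, length, numeric(1)))
  )
  structure(list(assay = assay, per_larva = per_larva, summary = smry),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("<response_summary> %s\n", x$assay))
  print(x$summary)
  invisible(x)
}

# sum a record field over bins whose start lies in [from, to), per well
.window_sum <- function(records, field, from, to) {
  sel <- records$bin_start_s >= from - 1e-9 & records$bin_start_s < to - 1e-9
  r <- records[sel, ]
  tapply(r[[field]], r$well_id, sum)
}

#' VMR transition response
#'
#' The visual motor response statistic: per larva, the burst duration within
#' `window_s` after each light transition of the requested direction,
#' averaged across trials; then group mean +/- SEM over larvae.
#'
#' @param records binned activity records with `bin_s <= window_s`.
#' @param protocol the `assay_protocol` that produced the records.
#' @param direction `"ON"` or `"OFF"`.
#' @param window_s response window in seconds after the transition
#'   (default 1).
#' @param response_field record field summed in the window.
#' @return a [response_summary()].
#' @export
vmr_response <- function(records, protocol, direction = c("ON", "OFF"),
                         window_s = 1, response_field = "dur_burst_s") {
  direction <- match.arg(direction)
  records <- tibble::as_tibble(records)
  bs <- unique(records$bin_s)
  stopifnot(length(bs) == 1L)
  if (bs > window_s) {
    stop("records are coarser than the response window", call. = FALSE)
  }
  tr <- transitions(protocol)
  tr <- tr[tr$direction == direction, ]
  if (nrow(tr) == 0L) {
    stop("protocol has no ", direction, " transitions", call. = FALSE)
  }
  wells <- unique(records$well_id)
  per_trial <- matrix(NA_real_, length(wells), nrow(tr),
                      dimnames = list(wells, NULL))
  n_bins_expected <- round(window_s / bs)
  for (j in seq_len(nrow(tr))) {
    t0 <- tr$time_s[j]
    sel <- records$bin_start_s >= t0 - 1e-9 &
      records$bin_start_s < t0 + window_s - 1e-9
    r <- records[sel, ]
    cnt <- tapply(r[[response_field]], r$well_id, length)[wells]
    val <- tapply(r[[response_field]], r$well_id, sum)[wells]
    val[!is.na(cnt) & cnt < n_bins_expected] <- NA
    per_trial[, j] <- as.numeric(val)
  }
  value <- unname(rowMeans(per_trial))
  if (anyNA(value)) {
    warning("larva(e) excluded for missing bins in the response window: ",
            paste(wells[is.na(value)], collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(value)
  geno <- records$genotype[match(wells, records$well_id)]
  response_summary(
    tibble::tibble(well_id = wells[keep], genotype = geno[keep],
                   value = value[keep]),
    assay = paste0("vmr_", tolower(direction))
  )
}

#' Percent response of a post window relative to a pre window
#'
#' The flash-response magnitude is expressed as the post-stimulus burst
#' duration as a percentage of the pre-stimulus burst duration,
#' `100 * post / pre` (a value of 100 means no change). When `pre` is zero
#' the response is undefined and `NA` is returned rather than an error.
#'
#' @param pre,post non-negative burst durations (seconds); vectorized.
#' @return percent values; `NA` where `pre == 0`.
#' @export
percent_response <- function(pre, post) {
  if (any(pre < 0, na.rm = TRUE) || any(post < 0, na.rm = TRUE)) {
    stop("pre and post must be >= 0", call. = FALSE)
  }
  ifelse(pre == 0, NA_real_, 100 * post / pre)
}

#' FSTR flash responses
#'
#' For each flash cue, the burst duration is summed over `window_s` before
#' and after flash onset per larva; the percent response is
#' [percent_response()] of the pair. Responses to forward and reverse
#' presentations of the same cue length are averaged per larva before group
#' summaries. Windows are snapped to the record bin grid (floor of the flash
#' time), since millisecond cues do not land on bin edges.
#'
#' @param records binned activity records (typically `bin_s = 1`).
#' @param protocols one `assay_protocol`, or a list of them (e.g. forward
#'   and reverse runs) each paired with its own records via `records` being
#'   a list of the same length.
#' @param window_s pre/post window length in seconds (default 30; the 1 s
#'   variant is also in use).
#' @return list with `per_larva` (tibble: `well_id`, `genotype`,
#'   `cue_ms`, `pre_s`, `post_s`, `percent`) and `summary` (a
#'   [response_summary()] per cue length on the percent scale).
#' @export
fstr_response <- function(records, protocols, window_s = 30) {
  if (inherits(protocols, "assay_protocol")) {
    protocols <- list(protocols)
    records <- list(records)
  }
  stopifnot(length(records) == length(protocols))
  runs <- lapply(seq_along(protocols), function(k) {
    pr <- protocols[[k]]
    rec <- tibble::as_tibble(records[[k]])
    bs <- unique(rec$bin_s)
    stopifnot(length(bs) == 1L)
    ep <- pr$epochs
    flashes <- which(ep$intensity_pct > 0)
    gap <- min(ep$duration_s[-flashes])
    if (window_s > gap) {
      stop("pre/post windows overlap between consecutive cues ",
           "(protocol misconfiguration)", call. = FALSE)
    }
    if (min(ep$start_s[flashes]) < window_s - 1e-9) {
      stop("first flash has less than window_s of recording before it",
           call. = FALSE)
    }
    wells <- unique(rec$well_id)
    geno <- rec$genotype[match(wells, rec$well_id)]
    do.call(rbind, lapply(flashes, function(i) {
      t0 <- floor(ep$start_s[i] / bs) * bs   # snap to bin grid
      pre <- .window_sum(rec, "dur_burst_s", t0 - window_s, t0)[wells]
      post <- .window_sum(rec, "dur_burst_s", t0, t0 + window_s)[wells]
      tibble::tibble(well_id = wells, genotype = geno,
                     cue_ms = round(ep$duration_s[i] * 1000),
                     pre_s = as.numeric(pre), post_s = as.numeric(post))
    }))
  })
  all <- do.call(rbind, runs)
  # average forward/reverse presentations of the same cue per larva
  key <- interaction(all$well_id, all$cue_ms, drop = TRUE)
  agg <- do.call(rbind, lapply(split(all, key), function(d) {
    tibble::tibble(well_id = d$well_id[1], genotype = d$genotype[1],
                   cue_ms = d$cue_ms[1],
                   pre_s = mean(d$pre_s), post_s = mean(d$post_s))
  }))
  agg$percent <- percent_response(agg$pre_s, agg$post_s)
  summaries <- lapply(split(agg, agg$cue_ms), function(d) {
    d_ok <- d[!is.na(d$percent), ]
    response_summary(
      tibble::tibble(well_id = d_ok$well_id, genotype = d_ok$genotype,
                     value = d_ok$percent),
      assay = sprintf("fstr_%dms", d$cue_ms[1])
    )
  })
  list(per_larva = tibble::as_tibble(agg), summary = summaries)
}

#' Free-swim activity summary
#'
#' Summaries of spontaneous locomotion under constant illumination: per
#' larva, the mean distance per 10 s bin and the mean per-bin coast and
#' burst durations; then group mean +/- SEM.
#'
#' @param records binned activity records from a constant-intensity
#'   protocol.
#' @param condition `"light"` or `"dark"` label attached to the summaries.
#' @return list of [response_summary()] objects: `distance` (mm per 10 s),
#'   `burst_duration` (s per bin), `coast_duration` (s per bin).
#' @export
freeswim_summary <- function(records, condition = c("light", "dark")) {
  condition <- match.arg(condition)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  bs <- unique(records$bin_s)
  if (length(bs) != 1L) stop("mixed bin_s in records", call. = FALSE)
  wells <- unique(records$well_id)
  geno <- records$genotype[match(wells, records$well_id)]
  per <- function(field, scale = 1) {
    v <- tapply(records[[field]], records$well_id, mean)[wells]
    tibble::tibble(well_id = wells, genotype = geno,
                   value = as.numeric(v) * scale)
  }
  dist <- tapply(records$dist_coast_mm + records$dist_burst_mm,
                 records$well_id, mean)[wells]
  list(
    distance = response_summary(
      tibble::tibble(well_id = wells, genotype = geno,
                     value = as.numeric(dist) * 10 / bs),
      assay = paste0("freeswim_", condition, "_dist_mm_per_10s")),
    burst_duration = response_summary(
      per("dur_burst_s"), paste0("freeswim_", condition, "_burst_s")),
    coast_duration = response_summary(
      per("dur_coast_s"), paste0("freeswim_", condition, "_coast_s"))
  )
}

#' Colour-maze preference summary
#'
#' Per-arm mean fish count over timepoints and the corresponding percentage
#' of the group. Supports the four-colour maze and the two-colour + neutral
#' variant; a neutral/centre column is treated like any other arm.
#'
#' @param counts tibble with a `timepoint` column and one count column per
#'   arm.
#' @param n_fish number of larvae in the maze; per-timepoint counts must sum
#'   to at most `n_fish` (fish in the uncounted centre make up the rest).
#' @return tibble with `arm`, `mean_count`, `sem_count`, `percent`.
#' @export
color_preference <- function(counts, n_fish) {
  counts <- tibble::as_tibble(counts)
  arms <- setdiff(names(counts), "timepoint")
  mat <- as.matrix(counts[, arms])
  sums <- rowSums(mat)
  if (any(sums > n_fish + 1e-9)) {
    stop("counts exceed n_fish at timepoint(s) ",
         paste(counts$timepoint[sums > n_fish], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    arm = arms,
    mean_count = unname(colMeans(mat)),
    sem_count = unname(apply(mat, 2, stats::sd)) / sqrt(nrow(mat)),
    percent = 100 * unname(colMeans(mat)) / n_fish
  )
}
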