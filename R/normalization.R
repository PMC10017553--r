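#' Three-step activity normalization
#'
#' Removes the three recognized nuisance sources in plate-based activity
#' data, in order:
#'
#' 1. *Well illumination*: each well's response is divided by its
#'    illumination factor — taken from a `well_mult` column in `metadata`
#'    when available (simulator ground truth), otherwise estimated as the
#'    well's mean activity over the whole recording divided by the plate
#'    mean.
#' 2. *Batch effect*: step-1 values are divided by the batch factor, the
#'    batch mean over the recording divided by the grand mean.
#' 3. *Baseline activity*: each well's mean step-2 value over the baseline
#'    window (by default the final 5 min of the pre-illumination adaptation
#'    epoch) is subtracted.
#'
#' Each step can be switched off. Degenerate (zero or non-finite) factors
#' are replaced by 1 with a warning and flagged in the report.
#'
#' @param records tibble of binned activity records (see [bin_activity()]).
#' @param metadata tibble with `well_id`, `batch`, and optionally
#'   `well_mult`; every record's well must appear here with a batch.
#' @param response_field column of `records` to normalize (e.g.
#'   `"dur_burst_s"`).
#' @param baseline_window numeric `c(start_s, end_s)`; default the last
#'   5 min of the first epoch, i.e. `c(first_epoch_end - 300,
#'   first_epoch_end)`. Must lie inside the recording.
#' @param protocol optional `assay_protocol` used to locate the default
#'   baseline window.
#' @param steps integer subset of `1:3`, the steps to apply.
#' @return list with `records` (input schema plus the normalized response in
#'   `response_field` and a logical `normalized` column) and `report` (class
#'   `normalization_report`: per-well illumination factors, per-batch
#'   factors, per-well baselines, steps applied, degenerate-factor flags).
#' @export
normalize_activity <- function(records, metadata, response_field = "dur_burst_s",
                               baseline_window = NULL, protocol = NULL,
                               steps = 1:3) {
  records <- tibble::as_tibble(records)
  stopifnot(response_field %in% names(records))
  if (!all(c("well_id", "batch") %in% names(metadata))) {
    stop("metadata needs well_id and batch columns", call. = FALSE)
  }
  m <- match(records$well_id, metadata$well_id)
  if (anyNA(m)) {
    stop("missing batch for well(s): ",
         paste(unique(records$well_id[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  batch <- metadata$batch[m]
  x <- records[[response_field]]
  rec_end <- max(records$bin_start_s + records$bin_s)

  if (is.null(baseline_window)) {
    if (!is.null(protocol)) {
      end1 <- protocol$epochs$start_s[1] + protocol$epochs$duration_s[1]
    } else {
      end1 <- 300
    }
    baseline_window <- c(max(0, end1 - 300), end1)
  }
  if (baseline_window[1] < 0 || baseline_window[2] > rec_end + 1e-9) {
    stop("baseline window must lie inside the recording", call. = FALSE)
  }

  wells <- unique(records$well_id)
  flags <- character(0)
  fix <- function(f, what) {
    bad <- !is.finite(f) | f <= 0
    if (any(bad)) {
      warning("degenerate ", what, " factor(s) set to 1: ",
              paste(names(f)[bad], collapse = ", "), call. = FALSE)
      flags <<- c(flags, paste0(what, ":", names(f)[bad]))
      f[bad] <- 1
    }
    f
  }

  # Step 1: well illumination factor
  if (1 %in% steps) {
    if ("well_mult" %in% names(metadata)) {
      wf <- stats::setNames(metadata$well_mult[match(wells, metadata$well_id)],
                            wells)
    } else {
      wm <- tapply(x, records$well_id, mean)[wells]
      wf <- stats::setNames(as.numeric(wm) / mean(x), wells)
    }
    wf <- fix(wf, "illumination")
    x <- x / wf[records$well_id]
  } else {
    wf <- stats::setNames(rep(1, length(wells)), wells)
  }

  # Step 2: batch factor
  batches <- unique(batch)
  if (2 %in% steps) {
    bm <- tapply(x, batch, mean)[batches]
    bf <- stats::setNames(as.numeric(bm) / mean(x), batches)
    bf <- fix(bf, "batch")
    x <- x / bf[batch]
  } else {
    bf <- stats::setNames(rep(1, length(batches)), batches)
  }

  # Step 3: baseline subtraction
  if (3 %in% steps) {
    in_base <- records$bin_start_s >= baseline_window[1] - 1e-9 &
      records$bin_start_s < baseline_window[2] - 1e-9
    if (!any(in_base)) {
      stop("no bins fall inside the baseline window", call. = FALSE)
    }
    base <- tapply(x[in_base], records$well_id[in_base], mean)[wells]
    base <- stats::setNames(as.numeric(base), wells)
    if (anyNA(base)) {
      warning("well(s) without baseline bins use baseline 0: ",
              paste(wells[is.na(base)], collapse = ", "), call. = FALSE)
      flags <- c(flags, paste0("baseline:", wells[is.na(base)]))
      base[is.na(base)] <- 0
    }
    x <- x - base[records$well_id]
  } else {
    base <- stats::setNames(rep(0, length(wells)), wells)
  }

  out <- records
  out[[response_field]] <- as.numeric(x)
  out$normalized <- TRUE
  report <- structure(
    list(response_field = response_field,
         well_factors = wf, batch_factors = bf, baselines = base,
         batch_of_record = batch,
         baseline_window = baseline_window,
         steps_applied = sort(steps), degenerate = flags),
    class = "normalization_report"
  )
  list(records = out, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf(
    "<normalization_report> field %s; steps %s; %d wells, %d batches; baseline [%g, %g] s\n",
    x$response_field, paste(x$steps_applied, collapse = ","),
    length(x$well_factors), length(x$batch_factors),
    x$baseline_window[1], x$baseline_window[2]))
  if (length(x$degenerate)) {
    cat("degenerate factors:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Invert a normalization
#'
#' Reconstructs the raw response from normalized records and the
#' [normalize_activity()] report, reversing the steps in reverse order.
#'
#' @param records normalized records.
#' @param report the `normalization_report`.
#' @return records with the raw response restored and `normalized = FALSE`.
#' @export
unnormalize_activity <- function(records, report) {
  stopifnot(inherits(report, "normalization_report"))
  x <- records[[report$response_field]]
  if (3 %in% report$steps_applied) {
    x <- x + report$baselines[records$well_id]
  }
  if (2 %in% report$steps_applied) {
    batch <- report$batch_of_record
    if (length(batch) != nrow(records)) {
      stop("report does not match records", call. = FALSE)
    }
    x <- x * report$batch_factors[batch]
  }
  if (1 %in% report$steps_applied) {
    x <- x * report$well_factors[records$well_id]
  }
  out <- records
  out[[report$response_field]] <- as.numeric(x)
  out$normalized <- FALSE
  out
}
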