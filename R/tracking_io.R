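#' Per-larva swim speed trace
#'
#' A thin container for one well's per-frame speed series plus plate
#' metadata. Speeds are instantaneous swim speeds in mm/s on a regular time
#' grid starting at recording time zero.
#'
#' @param well_id,genotype,batch character metadata.
#' @param frame_dt_s frame interval in seconds (> 0).
#' @param speeds numeric vector of non-negative, finite speeds (mm/s).
#' @return object of class `speed_trace`.
#' @export
speed_trace <- function(well_id, genotype, batch, frame_dt_s, speeds) {
  stopifnot(length(well_id) == 1L, length(frame_dt_s) == 1L, frame_dt_s > 0)
  if (length(speeds) == 0L) stop("trace must contain frames", call. = FALSE)
  if (any(!is.finite(speeds)) || any(speeds < 0)) {
    stop("speeds must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), genotype = as.character(genotype),
         batch = as.character(batch), frame_dt_s = frame_dt_s,
         speeds = as.numeric(speeds)),
    class = "speed_trace"
  )
}

#' @export
print.speed_trace <- function(x, ...) {
  cat(sprintf(
    "<speed_trace> well %s (%s, batch %s): %d frames @ %g s, mean %.2f mm/s\n",
    x$well_id, x$genotype, x$batch, length(x$speeds), x$frame_dt_s,
    mean(x$speeds)))
  invisible(x)
}

.record_cols <- c("well_id", "genotype", "batch", "bin_start_s", "bin_s",
                  "dur_inactive_s", "dur_coast_s", "dur_burst_s",
                  "dist_coast_mm", "dist_burst_mm",
                  "n_bouts_coast", "n_bouts_burst")

#' Write / read binned activity records as CSV
#'
#' The on-disk dialect is a plain CSV with a fixed header (the columns of
#' [bin_activity()] output, in order), period decimal separator, durations
#' at millisecond precision and distances at 0.001 mm. Reading validates the
#' header, the non-negativity of all numeric fields, that all rows share one
#' `bin_s`, and that per-row class durations sum to `bin_s` within one
#' millisecond times the bin's frame count tolerance (2% of `bin_s`).
#'
#' @param records tibble of binned activity records.
#' @param path CSV file path.
#' @return `write_records` returns `path` invisibly; `read_records` returns
#'   a tibble.
#' @export
write_records <- function(records, path) {
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0 && length(unique(records$bin_s)) != 1L) {
    stop("records must share a single `bin_s`", call. = FALSE)
  }
  missing <- setdiff(.record_cols, names(records))
  if (length(missing)) {
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- records[, .record_cols]
  for (col in c("dur_inactive_s", "dur_coast_s", "dur_burst_s")) {
    out[[col]] <- round(out[[col]], 3)
  }
  for (col in c("dist_coast_mm", "dist_burst_mm")) {
    out[[col]] <- round(out[[col]], 3)
  }
  utils::write.csv(as.data.frame(out), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, .record_cols)) {
    stop("unknown header in ", path, ": expected columns ",
         paste(.record_cols, collapse = ", "), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(well_id = "character",
                                       genotype = "character",
                                       batch = "character"))
  if (nrow(df) == 0L) return(tibble::as_tibble(df))
  num_cols <- .record_cols[4:12]
  for (col in num_cols) {
    if (!is.numeric(df[[col]])) {
      stop("column ", col, " is not numeric", call. = FALSE)
    }
    bad <- which(df[[col]] < 0 | !is.finite(df[[col]]))
    if (length(bad)) {
      stop("negative or non-finite value in column ", col, ", row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (length(unique(df$bin_s)) != 1L) {
    stop("mixed `bin_s` values in ", path, call. = FALSE)
  }
  dsum <- df$dur_inactive_s + df$dur_coast_s + df$dur_burst_s
  bad <- which(abs(dsum - df$bin_s) > pmax(0.02 * df$bin_s, 0.002))
  if (length(bad)) {
    stop("class durations do not sum to bin_s in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write / read speed traces as long-format CSV with a JSON sidecar
#'
#' Traces are stored one row per well-frame (`well_id`, `frame_idx`,
#' `speed_mm_s`, speeds at 1e-6 mm/s precision); shared metadata (schema
#' version, frame interval, per-well genotype and batch, optional protocol
#' hash and seed) lives in `<path>.json`.
#'
#' @param traces list of `speed_trace` objects sharing one `frame_dt_s`.
#' @param path CSV file path (sidecar written at `paste0(path, ".json")`).
#' @param protocol optional `assay_protocol`; a hash is stored in the sidecar.
#' @param seed optional integer recorded in the sidecar.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   list of `speed_trace`.
#' @export
write_traces <- function(traces, path, protocol = NULL, seed = NULL) {
  stopifnot(length(traces) >= 1L)
  dts <- unique(vapply(traces, function(x) x$frame_dt_s, numeric(1)))
  if (length(dts) != 1L) {
    stop("all traces must share one frame_dt_s", call. = FALSE)
  }
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(well_id = tr$well_id,
               frame_idx = seq_along(tr$speeds),
               speed_mm_s = round(tr$speeds, 6))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(
    schema_version = "1.0",
    frame_dt_s = dts,
    wells = lapply(traces, function(tr) {
      list(well_id = tr$well_id, genotype = tr$genotype, batch = tr$batch)
    }),
    protocol_hash = if (!is.null(protocol)) {
      sum(as.numeric(utf8ToInt(paste(
        format(protocol$epochs$intensity_pct), collapse = ","))))
    },
    seed = seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, c("well_id", "frame_idx", "speed_mm_s"))) {
    stop("unknown header in ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(well_id = "character"))
  lapply(meta$wells, function(w) {
    v <- df$speed_mm_s[df$well_id == w$well_id]
    speed_trace(w$well_id, w$genotype, w$batch,
                frame_dt_s = meta$frame_dt_s, speeds = v)
  })
}
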