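#' Dynamic acquisition framing schedule
#'
#' A framing schedule is the ordered list of frame start times and durations
#' (seconds) onto which list-mode PET data are re-binned. Frames must be
#' contiguous and non-overlapping, starting at 0 s.
#'
#' @param start_s Numeric vector of frame start times in seconds.
#' @param duration_s Numeric vector of frame durations in seconds (all > 0).
#' @return An object of class `framing_schedule`: a data frame with columns
#'   `start_s` and `duration_s`.
#' @examples
#' sched <- framing_schedule(c(0, 5, 10), c(5, 5, 10))
#' schedule_total_s(sched)
#' @export
framing_schedule <- function(start_s, duration_s) {
  start_s <- as.numeric(start_s)
  duration_s <- as.numeric(duration_s)
  if (length(start_s) != length(duration_s) || length(start_s) == 0L)
    stop("start_s and duration_s must be nonempty vectors of equal length")
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s)))
    stop("frame times must be finite")
  if (any(duration_s <= 0))
    stop("all frame durations must be > 0")
  if (abs(start_s[1L]) > 1e-9)
    stop("first frame must start at 0 s")
  if (length(start_s) > 1L) {
    expected <- start_s[-length(start_s)] + duration_s[-length(duration_s)]
    if (any(abs(start_s[-1L] - expected) > 1e-9))
      stop("frames must be contiguous and non-overlapping")
  }
  structure(data.frame(start_s = start_s, duration_s = duration_s),
            class = c("framing_schedule", "data.frame"))
}

#' Default 40-frame dynamic schedule
#'
#' The standard rest Rb-82 re-binning grid: 28 frames of 5 s followed by
#' 12 frames of 10 s, 260 s (about 4.3 min) in total.
#'
#' @return A [framing_schedule()] with 40 frames.
#' @export
default_framing_schedule <- function() {
  dur <- c(rep(5, 28), rep(10, 12))
  framing_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' @export
print.framing_schedule <- function(x, ...) {
  cat(sprintf("framing_schedule: %d frames, %.0f s total\n",
              nrow(x), schedule_total_s(x)))
  invisible(x)
}

#' Total duration of a schedule in seconds
#' @param schedule A [framing_schedule()].
#' @return Scalar seconds.
#' @export
schedule_total_s <- function(schedule) {
  stopifnot(inherits(schedule, "framing_schedule"))
  sum(schedule$duration_s)
}

#' Frame end times and midpoints
#' @param schedule A [framing_schedule()].
#' @return Numeric vector.
#' @keywords internal
frame_ends <- function(schedule) schedule$start_s + schedule$duration_s

#' @rdname frame_ends
#' @keywords internal
frame_mids <- function(schedule) schedule$start_s + schedule$duration_s / 2

#' Time-activity curve for one region
#'
#' Activity concentration (kBq/mL) per frame of a [framing_schedule()],
#' for a blood-pool or myocardial region. Values are frame averages of the
#' underlying continuous concentration; all corrections (decay, attenuation,
#' scatter, randoms) are assumed already applied upstream, recorded by the
#' `decay_corrected` flag. Negative values are permitted only when a noise
#' model was active (`noise_active = TRUE`).
#'
#' @param schedule A [framing_schedule()].
#' @param values Numeric vector, one activity concentration per frame.
#' @param region_label Character label for the region.
#' @param decay_corrected Logical; estimators refuse curves flagged `FALSE`.
#' @param noise_active Logical; whether a noise model produced these values.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, region_label = "region",
                decay_corrected = TRUE, noise_active = FALSE) {
  stopifnot(inherits(schedule, "framing_schedule"))
  values <- as.numeric(values)
  if (length(values) != nrow(schedule))
    stop(sprintf("length(values) = %d does not match schedule with %d frames",
                 length(values), nrow(schedule)))
  if (any(!is.finite(values)))
    stop("TAC values must be finite")
  if (!noise_active && any(values < 0))
    stop("negative TAC values are only permitted when noise_active = TRUE")
  structure(list(schedule = schedule, values = values,
                 region_label = as.character(region_label)[1L],
                 decay_corrected = isTRUE(decay_corrected),
                 noise_active = isTRUE(noise_active)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("tac '%s': %d frames, range [%.3g, %.3g] kBq/mL%s\n",
              x$region_label, length(x$values), min(x$values), max(x$values),
              if (x$noise_active) " (noisy)" else ""))
  invisible(x)
}

same_schedule <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    all(abs(a$start_s - b$start_s) < tol) &&
    all(abs(a$duration_s - b$duration_s) < tol)
}

#' Rectangle-rule integral of a TAC over a frame-aligned window
#'
#' Sums `value * duration` over all frames fully inside `[t0, t1)`; because
#' TAC values are frame averages this is the rectangle-rule integral of the
#' curve. The canonical use is the first-two-minutes arterial input integral
#' of the retention model. The window must be aligned to frame boundaries;
#' no silent interpolation is performed.
#'
#' @param x A [tac()].
#' @param t0,t1 Window bounds in seconds; `[t0, t1)` must align with frame
#'   boundaries of the schedule.
#' @return Scalar integral in kBq*s/mL.
#' @examples
#' tac1 <- tac(default_framing_schedule(), rep(1, 40))
#' frame_window_sum(tac1, 0, 120)  # 120
#' @export
frame_window_sum <- function(x, t0, t1) {
  stopifnot(inherits(x, "tac"))
  sched <- x$schedule
  edges <- c(sched$start_s, schedule_total_s(sched))
  if (t1 <= t0) stop("window must satisfy t0 < t1")
  if (min(abs(edges - t0)) > 1e-9 || min(abs(edges - t1)) > 1e-9)
    stop(sprintf("window [%g, %g) is not aligned to frame boundaries", t0, t1))
  inside <- sched$start_s >= t0 - 1e-9 & frame_ends(sched) <= t1 + 1e-9
  sum(x$values[inside] * sched$duration_s[inside])
}

#' Mean TAC value over a frame-aligned window
#'
#' Duration-weighted mean concentration over frames fully inside `[t0, t1)`;
#' used for the late-uptake myocardial image of the retention model.
#'
#' @inheritParams frame_window_sum
#' @return Scalar mean concentration in kBq/mL.
#' @export
frame_window_mean <- function(x, t0, t1) {
  frame_window_sum(x, t0, t1) / (t1 - t0)
}

# ---- I/O ------------------------------------------------------------------

#' Read and write time-activity curves
#'
#' Two pinned dialects. CSV: header row `start_s,duration_s,value_kBq_per_mL`,
#' comma separator, '.' decimal, UTF-8; round-trips values to at least 6
#' decimals. JSON: schedule, values and metadata; round-trips bit-exactly.
#'
#' @param x A [tac()] (write).
#' @param path File path.
#' @param dialect `"json"` or `"csv"`; inferred from the file extension when
#'   missing.
#' @return `read_tac()` returns a [tac()]; writers return `path` invisibly.
#' @export
write_tac <- function(x, path, dialect = c("auto", "json", "csv")) {
  stopifnot(inherits(x, "tac"))
  dialect <- resolve_dialect(match.arg(dialect), path)
  if (dialect == "csv") {
    df <- data.frame(start_s = x$schedule$start_s,
                     duration_s = x$schedule$duration_s,
                     value_kBq_per_mL = x$values)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    obj <- list(region_label = x$region_label,
                decay_corrected = x$decay_corrected,
                noise_active = x$noise_active,
                schedule = list(start_s = x$schedule$start_s,
                                duration_s = x$schedule$duration_s),
                values = x$values)
    # 17 significant digits: doubles survive the round-trip bit-exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path, dialect = c("auto", "json", "csv")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dialect <- resolve_dialect(match.arg(dialect), path)
  if (dialect == "csv") read_tac_csv(path) else read_tac_json(path)
}

resolve_dialect <- function(dialect, path) {
  if (dialect != "auto") return(dialect)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return("csv")
  if (ext == "json") return("json")
  stop(sprintf("cannot infer TAC dialect from extension '.%s'", ext))
}

read_tac_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop(sprintf("%s: no data rows", path))
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  need <- c("start_s", "duration_s", "value_kBq_per_mL")
  if (!all(need %in% header))
    stop(sprintf("%s: line 1: header must contain %s",
                 path, paste(need, collapse = ", ")))
  idx <- match(need, header)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) < length(header))
      stop(sprintf("%s: line %d: expected %d fields, found %d",
                   path, i, length(header), length(parts)))
    vals <- suppressWarnings(as.numeric(parts[idx]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop(sprintf("%s: line %d: non-numeric token '%s' in field '%s'",
                   path, i, parts[idx][bad[1L]], need[bad[1L]]))
    vals
  })
  m <- do.call(rbind, rows)
  sched <- tryCatch(framing_schedule(m[, 1L], m[, 2L]),
                    error = function(e)
                      stop(sprintf("%s: schedule invalid: %s",
                                   path, conditionMessage(e))))
  tac(sched, m[, 3L], region_label = tools::file_path_sans_ext(basename(path)),
      noise_active = any(m[, 3L] < 0))
}

read_tac_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("%s: JSON parse error: %s",
                                 path, conditionMessage(e))))
  need <- c("schedule", "values")
  if (!all(need %in% names(obj)))
    stop(sprintf("%s: missing fields: %s", path,
                 paste(setdiff(need, names(obj)), collapse = ", ")))
  sched <- framing_schedule(obj$schedule$start_s, obj$schedule$duration_s)
  if (length(obj$values) != nrow(sched))
    stop(sprintf("%s: %d values for %d frames", path,
                 length(obj$values), nrow(sched)))
  tac(sched, obj$values,
      region_label = obj$region_label %||% "region",
      decay_corrected = obj$decay_corrected %||% TRUE,
      noise_active = obj$noise_active %||% any(obj$values < 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write per-segment result tables
#'
#' CSV with columns `segment_id` (1-17, AHA numbering), `rmbf` (mL/min/g),
#' `ru_percent` (percent relative uptake of maximum) and optionally
#' `rest_score` (0-4).
#'
#' @param x A segment table (see [segment_table()]).
#' @param path File path.
#' @return `read_segment_table()` returns a validated segment table.
#' @export
write_segment_table <- function(x, path) {
  x <- segment_table(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_segment_table
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  segment_table(df)
}
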