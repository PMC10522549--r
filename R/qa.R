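#' Quality-assurance thresholds
#'
#' Operational thresholds of the eight-check automated screen. Only the
#' spillover bound (0.60) is an established printed constant; the remaining
#' thresholds are conservative defaults, exposed here so they are auditable
#' and adjustable.
#'
#' @param saturation_tol Relative tolerance of the saturation plateau:
#'   a run of at least `saturation_run` consecutive frames within this
#'   fraction of the global blood-curve maximum flags saturation. A hard
#'   clip yields exactly equal frames; a genuine smooth peak does not, so
#'   the tolerance is tight (0.002).
#' @param saturation_run Minimum plateau run length in frames.
#' @param arrival_frac Fraction of peak defining tracer arrival.
#' @param peak_window_bolus,peak_window_slow Allowed peak time after
#'   arrival (s), per infusion profile.
#' @param width_window_bolus,width_window_slow Allowed blood-curve FWHM (s).
#' @param tail_window_s Length of the late window for the tail-slope fit.
#' @param tail_slope_frac Flat-tail slope bound, as fraction of peak per
#'   second.
#' @param tail_level_frac Minimum tail level (fraction of peak) for the
#'   flat-tail flag (true tails decline toward low values).
#' @param motion_drift_sectors Gradual-motion bound on total centroid drift.
#' @param motion_jump_sectors Abrupt-motion bound on a single-frame jump.
#' @param motion_window_start_s Start of the motion-tracking window (s);
#'   earlier frames are blood-pool dominated and excluded.
#' @param spillover_bound Spillover fraction bound (printed value 0.60).
#' @param n_spillover_regions Number of lowest-uptake regions fitted for
#'   the spillover check.
#' @return An object of class `qa_config`.
#' @export
qa_config <- function(saturation_tol = 0.002, saturation_run = 2,
                      arrival_frac = 0.05,
                      peak_window_bolus = c(10, 90),
                      peak_window_slow = c(10, 150),
                      width_window_bolus = c(10, 45),
                      width_window_slow = c(20, 90),
                      tail_window_s = 60, tail_slope_frac = 0.001,
                      tail_level_frac = 0.30,
                      motion_drift_sectors = 1, motion_jump_sectors = 1,
                      motion_window_start_s = 60,
                      spillover_bound = 0.60, n_spillover_regions = 8) {
  structure(as.list(environment()), class = "qa_config")
}

curve_fwhm <- function(t, v) {
  half <- max(v) / 2
  above <- v >= half
  if (!any(above)) return(0)
  i1 <- which(above)[1L]
  i2 <- rev(which(above))[1L]
  t_lo <- if (i1 == 1L) t[1L] else
    stats::approx(v[(i1 - 1):i1], t[(i1 - 1):i1], xout = half)$y
  t_hi <- if (i2 == length(v)) t[length(v)] else
    stats::approx(v[i2:(i2 + 1)], t[i2:(i2 + 1)], xout = half)$y
  t_hi - t_lo
}

wrap_sectors <- function(d, n) ((d + n / 2) %% n) - n / 2

# Angular shift (sectors) of each frame's sector profile relative to the
# late-uptake reference pattern, by circular cross-correlation with
# parabolic sub-sector refinement. Rings rotate together, so profiles are
# summed over rings.
frame_shifts_sectors <- function(tissue, grid, ref_frames) {
  ns <- grid$n_sectors
  prof <- matrix(0, ns, ncol(tissue))
  for (r in c("basal", "mid", "apical")) {
    rows <- which(grid$ring == r)
    prof <- prof + pmax(tissue[rows, , drop = FALSE], 0)
  }
  ref <- rowMeans(prof[, ref_frames, drop = FALSE])
  ref <- ref - mean(ref)
  vapply(seq_len(ncol(prof)), function(f) {
    p <- prof[, f] - mean(prof[, f])
    cc <- vapply(0:(ns - 1), function(s)
      sum(p[((seq_len(ns) - 1 + s) %% ns) + 1] * ref), numeric(1))
    i <- which.max(cc)
    # parabolic refinement on the circular neighbourhood
    ym <- cc[((i - 2) %% ns) + 1]; y0 <- cc[i]; yp <- cc[(i %% ns) + 1]
    denom <- ym - 2 * y0 + yp
    frac <- if (abs(denom) > 1e-12) 0.5 * (ym - yp) / denom else 0
    wrap_sectors((i - 1) + frac, ns)
  }, numeric(1))
}

#' Automated quality screen of a dynamic study
#'
#' Reproduces the eight-check technical screen on a study's blood and
#' tissue curves: inconsistent frame duration, scanner saturation,
#' inaccurate blood-curve peak, inappropriate blood peak width, flat blood
#' curve tail, gradual patient motion, abrupt patient motion, and spillover
#' fraction above 0.60. Each detector reports a boolean flag plus its
#' numeric evidence so thresholds remain auditable; the report passes
#' overall iff all eight flags are clear. Deterministic.
#'
#' @param study A `phantom_study` (needs blood and tissue curves on one
#'   schedule; the first blood location is used).
#' @param config A [qa_config()].
#' @return An object of class `qa_report`: `flags` (named logical),
#'   `evidence` (named list) and `overall_pass`.
#' @export
qa_check <- function(study, config = qa_config()) {
  stopifnot(inherits(study, "phantom_study"))
  if (!length(study$blood)) stop("study has no blood curve")
  sched <- study$schedule
  blood <- study$blood[[1L]]
  v <- blood$values
  pk <- max(v)
  mids <- frame_mids(sched)
  flags <- c()
  ev <- list()

  # 1. inconsistent frame duration: observed vs declared, exact
  ev$frame_duration_max_dev_s <-
    max(abs(study$observed_duration_s - sched$duration_s))
  flags["inconsistent_frame_duration"] <- ev$frame_duration_max_dev_s > 0

  # 2. scanner saturation: plateau of near-identical frames at the maximum
  near <- v >= pk * (1 - config$saturation_tol)
  r <- rle(near)
  ev$saturation_run_frames <- max(c(0, r$lengths[r$values]))
  flags["scanner_saturation"] <-
    ev$saturation_run_frames >= config$saturation_run

  # 3/4. peak time and width
  arrival <- sched$start_s[which(v >= config$arrival_frac * pk)[1L]]
  peak_t <- mids[which.max(v)]
  ev$peak_time_post_arrival_s <- peak_t - arrival
  pw <- if (study$aif_profile == "slow_20") config$peak_window_slow
        else config$peak_window_bolus
  flags["inaccurate_blood_peak"] <-
    ev$peak_time_post_arrival_s < pw[1] | ev$peak_time_post_arrival_s > pw[2]
  ev$fwhm_s <- curve_fwhm(mids, v)
  ww <- if (study$aif_profile == "slow_20") config$width_window_slow
        else config$width_window_bolus
  flags["inappropriate_peak_width"] <- ev$fwhm_s < ww[1] | ev$fwhm_s > ww[2]

  # 5. flat blood tail: near-zero slope at a still-elevated level
  total <- schedule_total_s(sched)
  tail_i <- sched$start_s >= total - config$tail_window_s - 1e-9
  fit <- stats::lm.fit(cbind(1, mids[tail_i]), v[tail_i])
  ev$tail_slope_frac_peak_per_s <- abs(fit$coefficients[2L]) / pk
  ev$tail_level_frac_peak <- mean(v[tail_i]) / pk
  flags["flat_blood_tail"] <-
    ev$tail_slope_frac_peak_per_s < config$tail_slope_frac &
    ev$tail_level_frac_peak > config$tail_level_frac

  # 6/7. motion: angular shift of the myocardial pattern across frames,
  # tracked from motion_window_start_s on (earlier frames are blood-pool
  # dominated and carry no stable tissue pattern)
  use <- which(sched$start_s >= config$motion_window_start_s - 1e-9)
  late_ref <- which(sched$start_s[use] >= 140 - 1e-9)
  shifts <- frame_shifts_sectors(study$tissue[, use, drop = FALSE],
                                 study$grid, late_ref)
  steps <- wrap_sectors(diff(shifts), study$grid$n_sectors)
  ev$centroid_total_drift_sectors <- abs(shifts[length(shifts)] - shifts[1L])
  ev$centroid_max_jump_sectors <- if (length(steps)) max(abs(steps)) else 0
  flags["abrupt_motion"] <-
    ev$centroid_max_jump_sectors > config$motion_jump_sectors
  flags["gradual_motion"] <-
    ev$centroid_total_drift_sectors > config$motion_drift_sectors &
    !flags[["abrupt_motion"]]

  # 8. spillover: 1-TCM blood fraction fitted on the lowest-uptake regions
  late <- sched$start_s >= 140 - 1e-9
  uptake <- rowMeans(study$tissue[, late, drop = FALSE])
  ring <- which(study$grid$ring != "apex")
  low <- ring[order(uptake[ring])][seq_len(config$n_spillover_regions)]
  vbs <- vapply(low, function(i) {
    res <- fit_1tcm(blood, tac(sched, study$tissue[i, ],
                               noise_active = isTRUE(study$noise_active)))
    res$spillover_fraction
  }, numeric(1))
  ev$spillover_fraction_median <- stats::median(vbs, na.rm = TRUE)
  flags["spillover_gt_060"] <-
    ev$spillover_fraction_median > config$spillover_bound

  structure(list(flags = flags, evidence = ev,
                 overall_pass = !any(flags)),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("qa_report: %s\n",
              if (x$overall_pass) "PASS" else
                paste("FAIL:", paste(names(x$flags)[x$flags],
                                     collapse = ", "))))
  invisible(x)
}
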