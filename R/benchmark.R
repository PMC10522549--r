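#' Transmural-scar low-flow accuracy gate
#'
#' Compares a scar rMBF measurement against the literature-derived upper
#' bound for its measurement mode: an ROI value passes iff it is strictly
#' below 0.39 mL/min/g; a segmental value fails iff it exceeds
#' 0.44 mL/min/g (0.44 itself passes). Values above the gate indicate an
#' upward bias of the measurement chain, not viable tissue.
#'
#' @param value Measured scar rMBF, mL/min/g (>= 0).
#' @param mode `"roi"` or `"segmental"`.
#' @param constants Output of [reference_constants()].
#' @return List with `value`, `mode`, `threshold`, `pass`.
#' @examples
#' accuracy_gate(0.26, "roi")$pass        # TRUE
#' accuracy_gate(0.71, "segmental")$pass  # FALSE
#' @export
accuracy_gate <- function(value, mode = c("roi", "segmental"),
                          constants = reference_constants()) {
  mode <- match.arg(mode)
  if (!is.finite(value) || value < 0) stop("value must be finite and >= 0")
  thr <- if (mode == "roi") constants$roi_gate_ml_min_g
         else constants$segmental_gate_ml_min_g
  pass <- if (mode == "roi") value < thr else !(value > thr)
  list(value = value, mode = mode, threshold = thr, pass = pass)
}

#' Test-retest coefficient of variation
#'
#' COV between repeat scans of one quantity: the SD of the inter-scan
#' differences divided by the mean of the values. The differences are the
#' signed ordered pairs (i < j) and their SD uses the (n-1) denominator;
#' with exactly two scans the single difference d gets SD = |d|/sqrt(2)
#' (identical to the SD of the two values). The alternative per-scan
#' SD/mean convention is available via `method`.
#'
#' @param values Numeric vector of repeat measurements (>= 2, mean > 0).
#' @param method `"pairwise_diff"` (default) or `"sd_over_mean"`.
#' @return Dimensionless COV (0 for identical values).
#' @examples
#' cov_repeat(c(0.25, 0.25, 0.25))  # 0
#' @export
cov_repeat <- function(values, method = c("pairwise_diff", "sd_over_mean")) {
  method <- match.arg(method)
  if (length(values) < 2L) stop("need at least 2 repeat values")
  m <- mean(values)
  if (m <= 0) stop("mean of values must be > 0 for a COV")
  if (method == "sd_over_mean") return(stats::sd(values) / m)
  cmb <- utils::combn(seq_along(values), 2L)
  d <- values[cmb[2L, ]] - values[cmb[1L, ]]
  sd_d <- if (length(d) == 1L) abs(d) / sqrt(2) else stats::sd(d)
  sd_d / m
}

#' Median, IQR, mean and SD of a sample
#'
#' Quantiles use linear interpolation (type 7), pinned so that reports are
#' byte-identical across runs.
#'
#' @param values Nonempty numeric vector.
#' @return List with `median`, `q1`, `q3`, `mean`, `sd`, `n`.
#' @export
summarize_values <- function(values) {
  if (!length(values)) stop("cannot summarize an empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3],
       mean = mean(values), sd = stats::sd(values),
       n = length(values))
}

#' Benchmark configuration
#'
#' Settings of the full phantom benchmark: number of phantom patients,
#' estimator variant and arterial-input settings, noise, QA screening, and
#' the segmental criteria. Everything downstream is reproducible from
#' `(config, seed)`.
#'
#' @param n_phantoms Number of phantom patients.
#' @param seed Master seed.
#' @param variant Estimator variant (see [estimate_study()]).
#' @param input_location Arterial-input location label.
#' @param input_scale Multiplicative arterial-input scale (< 1 emulates an
#'   input-underestimating package).
#' @param noise_level,scan_jitter_sd,flow_jitter_sd Passed to
#'   [phantom_spec()].
#' @param n_rest_scans Rest scans per phantom (default 3).
#' @param qa Run the QA screen and exclude failing scans.
#' @param n_sectors Fine-grid sectors per ring.
#' @param scar_frac_range Range of scar sizes (fraction of LV) drawn per
#'   phantom.
#' @param fixed_dv Distribution volume for the fixed-DV variant.
#' @param criteria A [seg_scar_criteria()].
#' @param constants Output of [reference_constants()].
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_phantoms = 20, seed = 1,
                             variant = "retention",
                             input_location = "la_aorta",
                             input_scale = 1,
                             noise_level = 0.5, scan_jitter_sd = 0.07,
                             flow_jitter_sd = 0.07,
                             n_rest_scans = 3, qa = FALSE,
                             n_sectors = 72,
                             scar_frac_range = c(0.20, 0.32),
                             fixed_dv = 0.77,
                             criteria = seg_scar_criteria(),
                             constants = reference_constants()) {
  structure(as.list(environment()), class = "benchmark_config")
}

#' Run the phantom benchmark
#'
#' Simulates `n_phantoms` phantom patients, each with three consecutive
#' rest scans using both infusion profiles (the first two scans get the
#' bolus and the slow infusion in seeded-random order, the third either),
#' optionally screens scans with the QA checks (a failing scan is excluded;
#' a phantom keeping fewer than two scans is excluded from COV), estimates
#' rMBF per scan with the configured variant and input settings, runs the
#' scar analysis, applies the ROI and segmental accuracy gates, and
#' aggregates medians/IQRs, COVs and gate-exceedance fractions.
#'
#' @param config A [benchmark_config()].
#' @return An object of class `benchmark_report`: `rows` (one data-frame
#'   row per analyzed scan), `summary` (named list of aggregates) and a
#'   config echo.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  grid <- polar_grid(config$n_sectors)
  cfg <- retention_config()
  mid <- which(grid$ring == "mid")
  rows <- list()
  covs <- list()
  n_excluded <- 0L
  for (p in seq_len(config$n_phantoms)) {
    sp <- derive_seed(config$seed, p)
    draws <- with_seed(sp, list(
      center = sample(mid, 1L),
      frac = stats::runif(1, config$scar_frac_range[1],
                          config$scar_frac_range[2]),
      order12 = sample(c("bolus_50", "slow_20")),
      third = sample(c("bolus_50", "slow_20"), 1L)))
    fm <- ground_truth_flow_map(grid, scar_center = draws$center,
                                scar_frac_lv = draws$frac,
                                seed = derive_seed(sp, 11))
    profiles <- c(draws$order12, draws$third)[seq_len(config$n_rest_scans)]
    spec <- phantom_spec(
      fm, aif_per_scan = lapply(profiles, aif_params),
      n_rest_scans = config$n_rest_scans,
      noise_level = config$noise_level,
      scan_jitter_sd = config$scan_jitter_sd,
      flow_jitter_sd = config$flow_jitter_sd,
      rng_seed = derive_seed(sp, 12))
    studies <- simulate_phantom(spec)
    kept <- rep(TRUE, length(studies))
    if (config$qa) {
      kept <- vapply(studies, function(st) qa_check(st)$overall_pass,
                     logical(1))
      n_excluded <- n_excluded + sum(!kept)
    }
    phantom_rows <- list()
    for (s in which(kept)) {
      st <- studies[[s]]
      est <- estimate_study(st, variant = config$variant,
                            input_location = config$input_location,
                            cfg = cfg, fixed_dv = config$fixed_dv,
                            input_scale = config$input_scale)
      sa <- scar_analysis(est, grid, config$criteria)
      seg_vals <- if (length(sa$seg_scar))
        sa$segments$rmbf[sa$seg_scar] else numeric(0)
      truth_scar_mbf <- sum(fm$mbf[fm$scar_mask] * grid$area[fm$scar_mask]) /
        sum(grid$area[fm$scar_mask])
      phantom_rows[[length(phantom_rows) + 1L]] <- data.frame(
        phantom = p, scan = s, profile = st$aif_profile,
        roi_empty = sa$empty,
        roi_size_pct_lv = sa$roi_size_pct_lv,
        roi_mean_rmbf = sa$roi_mean_rmbf,
        roi_min_rmbf = sa$roi_min_rmbf,
        roi_mean_ru = sa$roi_mean_ru,
        n_seg_scar = length(sa$seg_scar),
        seg_scar_mean_rmbf = sa$seg_scar_mean_rmbf,
        lowest_segment_rmbf = sa$lowest_segment_rmbf,
        seg_border_mean_rmbf = sa$seg_border_mean_rmbf,
        seg_norm_mean_rmbf = sa$seg_norm_mean_rmbf,
        whole_heart_rmbf = sa$whole_heart_rmbf,
        n_seg_exceed = sum(seg_vals > config$constants$segmental_gate_ml_min_g),
        roi_gate_pass = if (sa$empty) NA else
          accuracy_gate(sa$roi_mean_rmbf, "roi", config$constants)$pass,
        seg_gate_pass = if (length(seg_vals))
          accuracy_gate(sa$seg_scar_mean_rmbf, "segmental",
                        config$constants)$pass else NA,
        truth_scar_mbf = truth_scar_mbf,
        truth_scar_frac = fm$scar_frac_lv)
    }
    pr <- do.call(rbind, phantom_rows)
    rows[[p]] <- pr
    if (!is.null(pr) && nrow(pr) >= 2L) {
      covs[[p]] <- data.frame(
        phantom = p,
        cov_whole_heart = cov_repeat(pr$whole_heart_rmbf),
        cov_roi_scar = if (all(!pr$roi_empty))
          cov_repeat(pr$roi_mean_rmbf) else NA_real_,
        cov_seg_scar = if (all(pr$n_seg_scar > 0))
          cov_repeat(pr$seg_scar_mean_rmbf) else NA_real_)
    }
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows))
    stop("no scans survived the QA screen")
  covs <- do.call(rbind, covs)
  med_iqr <- function(x) summarize_values(x[is.finite(x)])
  summary <- list(
    n_scans = nrow(rows),
    n_excluded_qa = n_excluded,
    roi_scar_rmbf = med_iqr(rows$roi_mean_rmbf),
    roi_min_rmbf = med_iqr(rows$roi_min_rmbf),
    roi_size_pct_lv = med_iqr(rows$roi_size_pct_lv),
    roi_mean_ru = med_iqr(rows$roi_mean_ru),
    seg_scar_rmbf = med_iqr(rows$seg_scar_mean_rmbf),
    lowest_segment_rmbf = med_iqr(rows$lowest_segment_rmbf),
    seg_border_rmbf = med_iqr(rows$seg_border_mean_rmbf),
    seg_norm_rmbf = med_iqr(rows$seg_norm_mean_rmbf),
    whole_heart_rmbf = med_iqr(rows$whole_heart_rmbf),
    roi_gate_pass_fraction = mean(rows$roi_gate_pass, na.rm = TRUE),
    pct_scans_seg_exceed =
      100 * mean(!rows$seg_gate_pass, na.rm = TRUE),
    pct_segments_exceed =
      100 * sum(rows$n_seg_exceed) / max(sum(rows$n_seg_scar), 1L),
    cov_whole_heart = if (!is.null(covs))
      stats::median(covs$cov_whole_heart, na.rm = TRUE) else NA_real_,
    cov_roi_scar = if (!is.null(covs))
      stats::median(covs$cov_roi_scar, na.rm = TRUE) else NA_real_,
    cov_seg_scar = if (!is.null(covs))
      stats::median(covs$cov_seg_scar, na.rm = TRUE) else NA_real_)
  structure(list(schema_version = "1.0",
                 config = config[setdiff(names(config),
                                         c("criteria", "constants"))],
                 rows = rows, covs = covs, summary = summary),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  s <- x$summary
  fmt <- function(z) sprintf("%.2f [%.2f-%.2f]", z$median, z$q1, z$q3)
  cat("benchmark_report\n")
  cat(sprintf("  scans analyzed: %d (QA-excluded: %d)\n",
              s$n_scans, s$n_excluded_qa))
  cat(sprintf("  ROI-Scar rMBF:  %s mL/min/g (gate <0.39 pass rate %.0f%%)\n",
              fmt(s$roi_scar_rmbf), 100 * s$roi_gate_pass_fraction))
  cat(sprintf("  Seg-Scar rMBF:  %s mL/min/g (%.0f%% of scans >0.44)\n",
              fmt(s$seg_scar_rmbf), s$pct_scans_seg_exceed))
  cat(sprintf("  whole heart:    %s mL/min/g, COV %.3f\n",
              fmt(s$whole_heart_rmbf), s$cov_whole_heart))
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Writes `report.json` (full report, pinned numeric formatting) and
#' `rows.csv` (per-scan detail). Identical `(config, seed)` produce
#' byte-identical files.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obj <- list(schema_version = report$schema_version,
              config = report$config[!vapply(report$config, is.object,
                                             logical(1))],
              summary = report$summary,
              covs = report$covs)
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  utils::write.csv(report$rows, file.path(dir, "rows.csv"),
                   row.names = FALSE)
  invisible(dir)
}
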