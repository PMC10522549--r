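#' Arterial input function parameters
#'
#' Parametric Rb-82 arterial input: a gamma-variate first pass plus a
#' declining recirculation tail. The slow-infusion profile is the same bolus
#' convolved with a normalized boxcar of `infusion_width_s` seconds (the
#' 50 vs 20 mL/min rate ratio at fixed syringe volume), which widens and
#' delays the peak while preserving delivered activity, so bolus and slow
#' infusion at equal dose have (near-)equal curve areas.
#'
#' @param profile `"bolus_50"` (50 mL/min bolus) or `"slow_20"`
#'   (20 mL/min slow infusion).
#' @param peak_time_s Time from tracer arrival to the first-pass peak (s).
#' @param peak_amplitude First-pass peak amplitude before any infusion
#'   smearing (kBq/mL); must be > 0.
#' @param width_shape Gamma-variate shape (dimensionless); larger = narrower.
#' @param tail_fraction Equilibrium recirculation tail amplitude as a
#'   fraction of the peak, in `[0, 1)`.
#' @param recirculation_fraction Amplitude of the delayed recirculation bump
#'   as a fraction of the peak.
#' @param arrival_s Tracer arrival time after scan start (s).
#' @param infusion_width_s Boxcar infusion duration (s); 0 for the bolus,
#'   36 for the slow infusion (50/20 of the 14.4-s bolus push).
#' @return An object of class `aif_params`.
#' @export
aif_params <- function(profile = c("bolus_50", "slow_20"),
                       peak_time_s = 15,
                       peak_amplitude = 100,
                       width_shape = 2.5,
                       tail_fraction = 0.12,
                       recirculation_fraction = 0.10,
                       arrival_s = 10,
                       infusion_width_s = NULL) {
  profile <- match.arg(profile)
  if (peak_amplitude <= 0) stop("peak_amplitude must be > 0")
  if (tail_fraction < 0 || tail_fraction >= 1)
    stop("tail_fraction must lie in [0, 1)")
  if (is.null(infusion_width_s))
    infusion_width_s <- if (profile == "bolus_50") 0 else 36
  structure(list(profile = profile, peak_time_s = peak_time_s,
                 peak_amplitude = peak_amplitude, width_shape = width_shape,
                 tail_fraction = tail_fraction,
                 recirculation_fraction = recirculation_fraction,
                 arrival_s = arrival_s, infusion_width_s = infusion_width_s),
            class = "aif_params")
}

#' Continuous arterial input model (before infusion smearing)
#'
#' Unit-peak gamma variate `g(u) = (u/tp)^a * exp(a*(1 - u/tp))` for
#' `u = t - arrival`, plus a recirculation bump (same form, delayed and
#' doubled in width) and a declining equilibrium tail
#' `tail_fraction * (1 - exp(-u/30)) * exp(-u/160)`.
#'
#' @param t Times (s).
#' @param p An [aif_params()].
#' @return Activity concentration at `t` (kBq/mL).
#' @export
aif_continuous <- function(t, p) {
  u <- pmax(t - p$arrival_s, 0)
  gv <- function(u, tp, a) ifelse(u <= 0, 0, (u / tp)^a * exp(a * (1 - u / tp)))
  first <- gv(u, p$peak_time_s, p$width_shape)
  recirc <- p$recirculation_fraction *
    gv(pmax(u - 2 * p$peak_time_s, 0), 2 * p$peak_time_s, p$width_shape)
  tail <- p$tail_fraction * (1 - exp(-u / 30)) * exp(-u / 160)
  p$peak_amplitude * (first + recirc + tail)
}

smear_infusion <- function(values_fine, width_s, dt = FINE_DT) {
  if (width_s <= 0) return(values_fine)
  k <- max(1L, round(width_s / dt))
  kern <- rep(1 / k, k)
  # causal moving average: pad with zeros before the scan
  out <- stats::filter(c(rep(0, k - 1L), values_fine), kern, sides = 1)
  as.numeric(out[k - 1L + seq_along(values_fine)])
}

#' Generate a frame-averaged arterial input TAC
#'
#' Evaluates the continuous input model on a fine sub-second grid, applies
#' the infusion boxcar for the slow profile, and averages within frames.
#' Deterministic for fixed parameters; `seed` is recorded for provenance.
#'
#' @param params An [aif_params()].
#' @param schedule A [framing_schedule()].
#' @param seed Optional integer recorded with the curve.
#' @param amplitude_scale Multiplicative scale on the whole curve (used for
#'   per-scan delivered-dose jitter).
#' @return A blood-pool [tac()] carrying its exact fine-grid representation.
#' @export
generate_aif <- function(params, schedule = default_framing_schedule(),
                         seed = NULL, amplitude_scale = 1) {
  stopifnot(inherits(params, "aif_params"))
  tt <- fine_times(schedule_total_s(schedule))
  v <- aif_continuous(tt, params)
  v <- smear_infusion(v, params$infusion_width_s)
  v <- v * amplitude_scale
  out <- tac(schedule, rebin_to_frames(v, schedule),
             region_label = paste0("blood_", params$profile))
  out$fine <- list(dt = FINE_DT, values = v)
  out$aif_params <- params
  out$seed <- seed
  out
}

#' Renkin-Crone flow-to-K1 conversion
#'
#' First-pass extraction of Rb-82 falls with flow:
#' `K1 = F * (1 - a*exp(-b/F))` with the generalized Renkin-Crone constants
#' `a = 0.77`, `b = 0.63` (mL/min/g) of the single-tissue Rb-82 model family.
#' Extraction tends to 1 as flow tends to 0, so `K1 <= F` and tracer uptake
#' is near-linear in flow at scar-level flows.
#'
#' @param mbf Flow in mL/min/g (vectorized, >= 0).
#' @param a,b Extraction constants.
#' @return K1 in mL/min/g.
#' @examples
#' renkin_crone_k1(1.0)   # ~0.590
#' renkin_crone_k1(0.25)  # ~0.234
#' @export
renkin_crone_k1 <- function(mbf, a = 0.77, b = 0.63) {
  if (any(mbf < 0)) stop("mbf must be >= 0")
  ifelse(mbf == 0, 0, mbf * (1 - a * exp(-b / mbf)))
}

#' Invert the Renkin-Crone conversion
#'
#' Monotone 1-D root find of [renkin_crone_k1()]; `k1 = 0` maps to 0.
#'
#' @param k1 Uptake rate constant K1 in mL/min/g (scalar or vector, >= 0).
#' @inheritParams renkin_crone_k1
#' @param upper Upper flow bound for the root search (mL/min/g).
#' @return Flow in mL/min/g.
#' @export
renkin_crone_mbf <- function(k1, a = 0.77, b = 0.63, upper = 20) {
  one <- function(k) {
    if (k < 0) stop("k1 must be >= 0")
    if (k == 0) return(0)
    if (k >= renkin_crone_k1(upper, a, b))
      stop(sprintf("k1 = %.3g outside invertible range", k))
    stats::uniroot(function(f) renkin_crone_k1(f, a, b) - k,
                   c(1e-12, upper), tol = 1e-10)$root
  }
  vapply(k1, one, numeric(1))
}

#' Forward one-tissue-compartment tissue curve
#'
#' Generates the measured myocardial TAC for a region with true flow `mbf`:
#' `C_t(t) = K1 * (C_a ** exp(-k2 t))` with `K1 = renkin_crone_k1(mbf)`,
#' then `measured = pv_recovery * C_t + spillover * C_a`, frame-averaged.
#' Provide the washout either as `k2` (1/min) or as a distribution volume
#' `dv` (mL/g, `k2 = K1/dv`).
#'
#' @param aif Blood-pool [tac()] (same schedule).
#' @param mbf True flow, mL/min/g.
#' @param k2 Washout rate, 1/min (alternative to `dv`).
#' @param dv Distribution volume, mL/g (alternative to `k2`).
#' @param pv_recovery Partial-volume recovery coefficient in (0, 1].
#' @param spillover Blood-to-myocardium spillover fraction in [0, 1).
#' @param schedule Optional schedule (defaults to the AIF's).
#' @param region_label Label for the returned curve.
#' @param rc_a,rc_b Renkin-Crone constants.
#' @return A [tac()] carrying its fine representation; the pure (unmixed,
#'   full-recovery) tissue curve is attached as `$pure_fine`.
#' @export
forward_tissue_tac <- function(aif, mbf, k2 = NULL, dv = NULL,
                               pv_recovery = 1, spillover = 0,
                               schedule = NULL, region_label = "tissue",
                               rc_a = 0.77, rc_b = 0.63) {
  stopifnot(inherits(aif, "tac"))
  if (is.null(schedule)) schedule <- aif$schedule
  if (!same_schedule(schedule, aif$schedule))
    stop("aif schedule does not match the requested schedule")
  if (pv_recovery <= 0 || pv_recovery > 1) stop("pv_recovery must be in (0,1]")
  if (spillover < 0 || spillover >= 1) stop("spillover must be in [0,1)")
  if (is.null(k2)) {
    if (is.null(dv)) stop("supply k2 (1/min) or dv (mL/g)")
    k1 <- renkin_crone_k1(mbf, rc_a, rc_b)
    k2 <- if (k1 > 0) k1 / dv else 0
  }
  k1 <- renkin_crone_k1(mbf, rc_a, rc_b)
  ca <- tac_fine(aif)
  pure <- (k1 / 60) * conv_exp_fine(ca$values, k2 / 60)
  meas_fine <- pv_recovery * pure + spillover * ca$values
  out <- tac(schedule, rebin_to_frames(meas_fine, schedule),
             region_label = region_label)
  out$fine <- list(dt = FINE_DT, values = meas_fine)
  out$pure_fine <- pure
  out$true_params <- list(mbf = mbf, k1 = k1, k2 = k2,
                          pv_recovery = pv_recovery, spillover = spillover)
  out
}

# ---- ground truth flow map ------------------------------------------------

#' Ground-truth flow map with a contiguous transmural scar
#'
#' Builds the per-region truth for one phantom patient on a [polar_grid()]:
#' a contiguous scar mask, a one-layer border band around it, and normal
#' myocardium elsewhere. The default scar is a full-thickness
#' coronary-territory wedge: an angular span covering all three rings
#' (base to apex), sized to the target %LV area, so that the scar fully
#' covers central segments and partially covers the edge segments - the
#' geometry behind the ROI-versus-segment admixture effect. A compact
#' region grown from the seed sector is available via `shape = "blob"`. True
#' resting MBF is drawn uniformly per region within the stratum band
#' (defaults: scar 0.15-0.35, border 0.35-0.60, normal 0.55-1.00 mL/min/g).
#' Each stratum also carries a distribution volume: normal 4.0, border 2.0,
#' scar 2.0 mL/g; the reduced scar DV encodes the loss of the
#' potassium-analog distribution space in non-viable tissue and is what
#' depresses scar relative uptake to the ~40-47 %RU regime typical of
#' transmural scar.
#'
#' @param grid A [polar_grid()].
#' @param scar_center Index of the seed region (the wedge is centred on its
#'   angle); default mid-ring inferior.
#' @param scar_frac_lv Target scar area as a fraction of total LV area.
#' @param shape `"wedge"` (transmural coronary-territory wedge, default) or
#'   `"blob"` (compact region grown from the seed).
#' @param scar_band,border_band,normal_band Uniform truth bands (mL/min/g).
#' @param dv_scar,dv_border,dv_normal Distribution volumes (mL/g).
#' @param seed RNG seed for the truth draws.
#' @return An object of class `flow_map`: list with `mbf`, `dv`, `stratum`,
#'   masks, `scar_frac_lv` (achieved) and the grid.
#' @export
ground_truth_flow_map <- function(grid = polar_grid(),
                                  scar_center = NULL,
                                  scar_frac_lv = 0.26,
                                  shape = c("wedge", "blob"),
                                  scar_band = c(0.15, 0.35),
                                  border_band = c(0.35, 0.60),
                                  normal_band = c(0.55, 1.00),
                                  dv_scar = 1.2, dv_border = 2.0,
                                  dv_normal = 4.0, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(inherits(grid, "polar_grid"))
  if (scar_frac_lv <= 0 || scar_frac_lv >= 0.8)
    stop("scar_frac_lv must be in (0, 0.8)")
  if (is.null(scar_center)) {
    # mid-ring sector nearest the inferior wall (270 deg)
    mid <- which(grid$ring == "mid")
    scar_center <- mid[which.min(abs(grid$theta[mid] - 270))]
  }
  total_area <- sum(grid$area)
  scar <- logical(grid$n)
  if (shape == "wedge") {
    # angular span across all 3 rings whose sector area hits the target %LV
    span <- scar_frac_lv * total_area / 3 * (360 / grid$n_sectors)
    lo <- (grid$theta[scar_center] - span / 2) %% 360
    ring_i <- which(grid$ring != "apex")
    scar[ring_i] <- angle_in_span(grid$theta[ring_i], lo, lo + span)
  } else {
    scar[scar_center] <- TRUE
    queue <- grid$adj[[scar_center]]
    while (sum(grid$area[scar]) / total_area < scar_frac_lv &&
           length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (scar[v]) next
      scar[v] <- TRUE
      queue <- c(queue, setdiff(grid$adj[[v]], which(scar)))
    }
  }
  border <- logical(grid$n)
  border[unique(unlist(grid$adj[scar]))] <- TRUE
  border <- border & !scar
  stratum <- ifelse(scar, "scar", ifelse(border, "border", "normal"))
  bands <- list(scar = scar_band, border = border_band, normal = normal_band)
  dvs <- c(scar = dv_scar, border = dv_border, normal = dv_normal)
  mbf <- with_seed(seed, {
    m <- numeric(grid$n)
    for (s in names(bands))
      m[stratum == s] <- stats::runif(sum(stratum == s),
                                      bands[[s]][1], bands[[s]][2])
    m
  })
  structure(list(grid = grid, mbf = mbf, dv = unname(dvs[stratum]),
                 stratum = stratum, scar_mask = scar, border_mask = border,
                 scar_frac_lv = sum(grid$area[scar]) / total_area,
                 seed = seed),
            class = "flow_map")
}

#' @export
print.flow_map <- function(x, ...) {
  cat(sprintf("flow_map: %d regions, scar %.1f%% LV, scar MBF %.2f-%.2f\n",
              x$grid$n, 100 * x$scar_frac_lv,
              min(x$mbf[x$scar_mask]), max(x$mbf[x$scar_mask])))
  invisible(x)
}

#' Phantom study specification
#'
#' Everything needed to simulate one phantom patient reproducibly: the truth
#' flow map, the arterial input parameters (optionally per scan, mirroring
#' the rest protocol of three consecutive scans with two infusion profiles),
#' partial-volume recovery, per-stratum blood spillover, the frame-noise
#' level, per-scan delivered-activity jitter, an artifact plan, and the RNG
#' seed (recorded in every output).
#'
#' @param flow_map A [ground_truth_flow_map()].
#' @param aif An [aif_params()] used for every scan, unless `aif_per_scan`
#'   is given.
#' @param aif_per_scan Optional list of [aif_params()], one per scan.
#' @param n_rest_scans Number of consecutive rest scans (default 3).
#' @param pv_recovery Partial-volume recovery coefficient (default 0.85).
#' @param spillover Named per-stratum blood spillover fractions.
#' @param noise_level Frame-noise scale: the per-frame Gaussian SD is
#'   `noise_level * sqrt(value / duration)`, mimicking count statistics of
#'   frame-averaged corrected data. 0 disables frame noise.
#' @param scan_jitter_sd Lognormal SD of the per-scan delivered-activity
#'   scale (injection-to-injection variation). This cancels in any
#'   ratio-based flow estimate; it is kept for realism of the raw curves.
#'   0 disables it.
#' @param flow_jitter_sd Lognormal SD of the per-scan global physiologic
#'   flow scale: resting MBF genuinely varies between repeat scans with the
#'   subject's hemodynamic state, and this - not count noise - dominates
#'   test-retest variability of regional means. 0 disables it.
#' @param artifact_plan List of `list(scan =, kind =, params = list())`
#'   artifact injections (see [inject_artifact()]).
#' @param rng_seed Master seed; all per-scan noise streams derive from it.
#' @param schedule Framing schedule (default the 40-frame rest schedule).
#' @param input_bias Named list of arterial-input sampling-location biases,
#'   each `c(scale =, contamination =)`: the blood curve offered at that
#'   location is `scale * C_a + contamination * mean myocardial curve`.
#'   The left atrium / aorta location is the unbiased reference.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(flow_map,
                         aif = aif_params("bolus_50"),
                         aif_per_scan = NULL,
                         n_rest_scans = 3,
                         pv_recovery = 0.85,
                         spillover = c(scar = 0.35, border = 0.25,
                                       normal = 0.20),
                         noise_level = 0.5,
                         scan_jitter_sd = 0.07,
                         flow_jitter_sd = 0.07,
                         artifact_plan = list(),
                         rng_seed = 1,
                         schedule = default_framing_schedule(),
                         input_bias = default_input_bias()) {
  stopifnot(inherits(flow_map, "flow_map"))
  if (n_rest_scans < 1) stop("n_rest_scans must be >= 1")
  if (pv_recovery <= 0 || pv_recovery > 1) stop("pv_recovery must be in (0,1]")
  if (any(spillover < 0) || any(spillover >= 1))
    stop("spillover fractions must be in [0,1)")
  if (!is.null(aif_per_scan) && length(aif_per_scan) != n_rest_scans)
    stop("aif_per_scan must have one entry per scan")
  structure(list(flow_map = flow_map, aif = aif, aif_per_scan = aif_per_scan,
                 n_rest_scans = as.integer(n_rest_scans),
                 pv_recovery = pv_recovery, spillover = spillover,
                 noise_level = noise_level, scan_jitter_sd = scan_jitter_sd,
                 flow_jitter_sd = flow_jitter_sd,
                 artifact_plan = artifact_plan,
                 rng_seed = as.integer(rng_seed), schedule = schedule,
                 input_bias = input_bias),
            class = "phantom_spec")
}

#' Default arterial-input sampling-location biases
#'
#' Upward MBF bias across software packages is chiefly attributable to an
#' underestimated arterial input; fixed-location input ROIs (LV cavity,
#' mitral-valve plane) are modeled as a multiplicative underestimation of
#' the true input plus a myocardial-contamination admixture. The values are
#' illustrative mechanisms, not estimates of any vendor.
#'
#' @return Named list of `c(scale, contamination)` per location.
#' @export
default_input_bias <- function() {
  list(la_aorta = c(scale = 1.00, contamination = 0.00),
       lv_cavity = c(scale = 0.90, contamination = 0.05),
       mv_plane = c(scale = 0.80, contamination = 0.10))
}

#' Simulate a phantom patient's rest scans
#'
#' Produces one `phantom_study` per rest scan: the arterial input (scaled by
#' the per-scan delivered-activity jitter), blood curves per candidate input
#' location (with the location's bias), the measured tissue TAC per fine
#' region (forward one-tissue model with flow-dependent extraction, partial
#' volume, spillover, then frame noise), and the artifact plan applied to
#' its designated scans. Noise realizations are independent across scans but
#' reproducible from `(rng_seed, scan index)`; with `noise_level = 0`,
#' `scan_jitter_sd = 0` and no artifacts the studies are deterministic
#' functions of the spec.
#'
#' @param spec A [phantom_spec()].
#' @return List of `phantom_study` objects (length `n_rest_scans`).
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  fm <- spec$flow_map
  grid <- fm$grid
  if (max(mask_components(fm$scar_mask, grid$adj)) > 1L)
    stop("scar mask is not contiguous")
  sched <- spec$schedule
  lapply(seq_len(spec$n_rest_scans), function(s) {
    p <- if (!is.null(spec$aif_per_scan)) spec$aif_per_scan[[s]] else spec$aif
    amp <- if (spec$scan_jitter_sd > 0)
      with_seed(derive_seed(spec$rng_seed, s, 1),
                exp(stats::rnorm(1, 0, spec$scan_jitter_sd)))
    else 1
    aif_tac <- generate_aif(p, sched, amplitude_scale = amp)
    ca_fine <- aif_tac$fine$values
    ca_frames <- aif_tac$values

    flow_scale <- if (spec$flow_jitter_sd > 0)
      with_seed(derive_seed(spec$rng_seed, s, 4),
                exp(stats::rnorm(1, 0, spec$flow_jitter_sd)))
    else 1
    k1 <- renkin_crone_k1(fm$mbf * flow_scale)
    k2 <- ifelse(k1 > 0, k1 / fm$dv, 0)
    pure <- t(vapply(seq_len(grid$n), function(i) {
      (k1[i] / 60) * conv_exp_fine(ca_fine, k2[i] / 60)
    }, numeric(length(ca_fine))))
    pure_frames <- t(apply(pure, 1L, rebin_to_frames, schedule = sched))
    sp <- unname(spec$spillover[fm$stratum])
    clean <- spec$pv_recovery * pure_frames +
      outer(sp, ca_frames)

    noisy <- spec$noise_level > 0
    tissue <- clean
    if (noisy) {
      tissue <- tissue + with_seed(derive_seed(spec$rng_seed, s, 2), {
        sd <- spec$noise_level *
          sqrt(pmax(clean, 0.5) / rep(sched$duration_s, each = nrow(clean)))
        matrix(stats::rnorm(length(clean), 0, sd), nrow = nrow(clean))
      })
    }

    # mean myocardial curve for input-location contamination
    mean_tissue_fine <- colSums(pure * grid$area * spec$pv_recovery) /
      sum(grid$area)
    blood <- lapply(names(spec$input_bias), function(loc) {
      bb <- spec$input_bias[[loc]]
      vfine <- bb[["scale"]] * ca_fine +
        bb[["contamination"]] * mean_tissue_fine
      vframes <- rebin_to_frames(vfine, sched)
      if (noisy) {
        vframes <- vframes + with_seed(
          derive_seed(spec$rng_seed, s, 3, match(loc, names(spec$input_bias))),
          stats::rnorm(length(vframes), 0,
                       spec$noise_level *
                         sqrt(pmax(vframes, 0.5) / sched$duration_s)))
      }
      bt <- tac(sched, vframes, region_label = paste0("blood_", loc),
                noise_active = noisy)
      bt$fine <- list(dt = FINE_DT, values = vfine)
      bt
    })
    names(blood) <- names(spec$input_bias)

    study <- structure(list(
      schedule = sched,
      observed_duration_s = sched$duration_s,
      blood = blood,
      tissue = tissue,
      clean_tissue = clean,
      ca_frames_clean = ca_frames,
      pure_tissue = pure_frames,
      grid = grid,
      truth = fm,
      scan_index = s,
      aif_profile = p$profile,
      pv_recovery = spec$pv_recovery,
      spillover = sp,
      noise_active = noisy,
      meta = list(rng_seed = spec$rng_seed, scan = s,
                  amplitude_scale = amp, flow_scale = flow_scale,
                  noise_level = spec$noise_level,
                  scan_jitter_sd = spec$scan_jitter_sd,
                  flow_jitter_sd = spec$flow_jitter_sd)),
      class = "phantom_study")
    for (art in spec$artifact_plan) {
      if (identical(art$scan, s) || isTRUE(is.null(art$scan)))
        study <- inject_artifact(study, art$kind, art$params %||% list())
    }
    study
  })
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf(
    "phantom_study: scan %d (%s), %d regions x %d frames%s\n",
    x$scan_index, x$aif_profile, nrow(x$tissue), ncol(x$tissue),
    if (length(x$artifacts_applied %||% character()))
      paste0(", artifacts: ", paste(x$artifacts_applied, collapse = ", "))
    else ""))
  invisible(x)
}

#' The eight injectable technical artifacts
#'
#' @return Character vector of artifact kinds understood by
#'   [inject_artifact()], one per automated QA check.
#' @export
artifact_kinds <- function() {
  c("inconsistent_frame_duration", "scanner_saturation",
    "inaccurate_blood_peak", "inappropriate_peak_width",
    "flat_blood_tail", "gradual_motion", "abrupt_motion",
    "spillover_excess")
}

rotate_ring <- function(values, shift) {
  # circular shift by a possibly fractional number of sectors
  n <- length(values)
  if (shift == 0) return(values)
  lo <- floor(shift); frac <- shift - lo
  idx <- function(k) ((seq_len(n) - 1 - k) %% n) + 1
  (1 - frac) * values[idx(lo)] + frac * values[idx(lo + 1)]
}

apply_rotation <- function(tissue, grid, shift_per_frame) {
  for (r in c("basal", "mid", "apical")) {
    rows <- which(grid$ring == r)
    for (f in seq_len(ncol(tissue))) {
      if (shift_per_frame[f] != 0)
        tissue[rows, f] <- rotate_ring(tissue[rows, f], shift_per_frame[f])
    }
  }
  tissue
}

#' Inject a technical artifact into a simulated study
#'
#' Modifies a `phantom_study` to carry one of the eight technical error
#' modes the automated QA screen detects. Defaults are the severities at
#' which each artifact is expected to trip exactly its own QA flag.
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{inconsistent_frame_duration}{`frame` (default 5), `new_duration_s`
#'     (default 6): the recorded duration of one frame disagrees with the
#'     declared schedule.}
#'   \item{scanner_saturation}{`ceiling_frac` (default 0.8): blood curves are
#'     clipped at that fraction of the pre-artifact peak (detector plateau).}
#'   \item{inaccurate_blood_peak}{`delay_s` (default 80), `leak_frac`
#'     (default 0.08): the main bolus is delayed with a small early tracer
#'     leak, so the peak is late but its width is unchanged.}
#'   \item{inappropriate_peak_width}{`width_s` (default 80 bolus / 130
#'     slow): blood curves are smeared with a boxcar of that width.}
#'   \item{flat_blood_tail}{`from_s` (default 140), `level_frac` (default
#'     0.35): the tail is replaced by a constant at that fraction of peak.}
#'   \item{gradual_motion}{`total_shift_sectors` (default 2): tissue sectors
#'     rotate linearly from 0 to the total shift across the scan.}
#'   \item{abrupt_motion}{`t_step_s` (default 130), `shift_sectors` (default
#'     2): a step rotation from `t_step_s` onward.}
#'   \item{spillover_excess}{`fraction` (default 0.7): measured tissue is
#'     re-mixed with that blood spillover fraction.}
#' }
#'
#' @param study A `phantom_study` from [simulate_phantom()].
#' @param kind One of [artifact_kinds()].
#' @param params Named list of parameters (see Details).
#' @return The modified study, with `kind` appended to `artifacts_applied`.
#' @export
inject_artifact <- function(study, kind, params = list()) {
  stopifnot(inherits(study, "phantom_study"))
  if (!kind %in% artifact_kinds())
    stop(sprintf("unknown artifact kind '%s'", kind))
  sched <- study$schedule
  g <- function(name, default) params[[name]] %||% default

  mod_blood <- function(fun_fine) {
    study$blood <- lapply(study$blood, function(b) {
      vf <- fun_fine(b$fine$values)
      b$fine$values <- vf
      b$values <- rebin_to_frames(vf, sched)
      b
    })
    study
  }

  study <- switch(kind,
    inconsistent_frame_duration = {
      f <- g("frame", 5L); d <- g("new_duration_s", 6)
      study$observed_duration_s[f] <- d
      study
    },
    scanner_saturation = {
      frac <- g("ceiling_frac", 0.8)
      mod_blood(function(v) pmin(v, frac * max(v)))
    },
    inaccurate_blood_peak = {
      # delayed main bolus with a small immediate tracer leak (infusion
      # stutter): arrival is seen on time, the peak comes late, the peak
      # width is untouched
      delay <- g("delay_s", 100); leak <- g("leak_frac", 0.08)
      mod_blood(function(v) {
        tt <- fine_times(schedule_total_s(sched))
        pk <- max(v)
        arr <- tt[which(v >= 0.05 * pk)[1L]]
        shifted <- stats::approx(tt + delay, v, xout = tt, rule = 1)$y
        shifted[is.na(shifted)] <- 0
        step <- leak * pk * pmin(pmax((tt - arr) / 5, 0), 1) *
          (tt < arr + delay)
        pmax(shifted, step)
      })
    },
    inappropriate_peak_width = {
      w <- g("width_s", if (study$aif_profile == "bolus_50") 80 else 130)
      mod_blood(function(v) smear_infusion(v, w))
    },
    flat_blood_tail = {
      from <- g("from_s", 140); lev <- g("level_frac", 0.35)
      mod_blood(function(v) {
        tt <- fine_times(schedule_total_s(sched))
        v[tt >= from] <- lev * max(v)
        v
      })
    },
    gradual_motion = {
      shift <- g("total_shift_sectors", 2)
      nfr <- ncol(study$tissue)
      study$tissue <- apply_rotation(study$tissue, study$grid,
                                     shift * (seq_len(nfr) - 1) / (nfr - 1))
      study
    },
    abrupt_motion = {
      t0 <- g("t_step_s", 130); shift <- g("shift_sectors", 2)
      study$tissue <- apply_rotation(study$tissue, study$grid,
                                     shift * (sched$start_s >= t0))
      study
    },
    spillover_excess = {
      frac <- g("fraction", 0.7)
      noise <- study$tissue - study$clean_tissue
      remixed <- study$pv_recovery * study$pure_tissue +
        outer(rep(frac, nrow(study$tissue)), study$ca_frames_clean)
      study$tissue <- remixed + noise
      study$clean_tissue <- remixed
      study$spillover <- rep(frac, nrow(study$tissue))
      study
    })
  study$artifacts_applied <- c(study$artifacts_applied %||% character(), kind)
  study
}
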