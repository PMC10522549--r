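# Shared fixtures, built in code at test time.

default_bolus_aif <- function() generate_aif(aif_params("bolus_50"))
default_slow_aif <- function() generate_aif(aif_params("slow_20"))

# a quiet phantom: no frame noise, no scan-to-scan variation
noiseless_spec <- function(fm, ...) {
  phantom_spec(fm, noise_level = 0, scan_jitter_sd = 0, flow_jitter_sd = 0,
               ...)
}

small_grid <- function() polar_grid(24)

# wedge deliberately misaligned with segment boundaries so that the scar
# partially covers its edge segments (the ROI-vs-segment admixture premise)
partial_coverage_flow_map <- function(grid, i, frac = NULL) {
  if (is.null(frac)) frac <- 0.27 + 0.04 * ((i - 1) %% 20) / 19
  span <- frac * sum(grid$area) / 3 * (360 / grid$n_sectors)
  boundary <- 60 * (i %% 6)
  ctr_theta <- (boundary + span / 2) %% 360
  mid <- which(grid$ring == "mid")
  ctr <- mid[which.min(abs(grid$theta[mid] - ctr_theta))]
  ground_truth_flow_map(grid, scar_center = ctr, scar_frac_lv = frac,
                        seed = 5000 + i)
}

# 1-TCM measurement in the fit's own parametrization:
# (1 - vb) * K1 * (Ca ** exp(-k2 t)) + vb * Ca
tcm_measurement <- function(aif, k1, k2, vb) {
  pure <- forward_tissue_tac(aif, renkin_crone_mbf(k1), k2 = k2,
                             pv_recovery = 1, spillover = 0)
  tac(aif$schedule, (1 - vb) * pure$values + vb * aif$values)
}
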