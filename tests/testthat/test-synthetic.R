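test_that("bolus and slow infusion relate as rate ratio demands", {
  ab <- default_bolus_aif()
  as_ <- default_slow_aif()
  # earlier and higher bolus peak
  expect_lt(which.max(ab$values), which.max(as_$values))
  expect_gt(max(ab$values), max(as_$values))
  # equal injected dose: whole-scan areas agree within 5%
  area_b <- frame_window_sum(ab, 0, 260)
  area_s <- frame_window_sum(as_, 0, 260)
  expect_lt(abs(area_s / area_b - 1), 0.05)
})

test_that("frame-averaged AIF matches quadrature of the continuous form", {
  p <- aif_params("bolus_50")
  ab <- generate_aif(p)
  oracle <- integrate(function(t) aif_continuous(t, p), 0, 120,
                      rel.tol = 1e-9, subdivisions = 1000L)$value
  expect_lt(abs(frame_window_sum(ab, 0, 120) / oracle - 1), 0.02)
})

test_that("a tail-free AIF washes out to near zero late in the scan", {
  p <- aif_params("bolus_50", tail_fraction = 0, recirculation_fraction = 0)
  ab <- generate_aif(p)
  expect_lt(frame_window_mean(ab, 200, 260), 0.01 * max(ab$values))
  expect_error(aif_params(peak_amplitude = 0), "amplitude")
  expect_error(aif_params(tail_fraction = 1), "tail_fraction")
})

test_that("Renkin-Crone conversion matches direct evaluation and inverts", {
  expect_equal(renkin_crone_k1(0), 0)
  # direct evaluation of F*(1 - 0.77*exp(-0.63/F))
  expect_equal(renkin_crone_k1(1.0), 1 - 0.77 * exp(-0.63), tolerance = 1e-12)
  expect_equal(renkin_crone_k1(1.0), 0.590, tolerance = 1e-3)
  expect_equal(renkin_crone_k1(0.25), 0.234, tolerance = 1e-2)
  # extraction ~0.94 at scar flow: near-linear tracer behavior
  expect_equal(renkin_crone_k1(0.25) / 0.25, 0.938, tolerance = 1e-3)
  expect_true(all(renkin_crone_k1(c(0.1, 0.5, 2)) <= c(0.1, 0.5, 2)))
  fs <- c(0.05, 0.15, 0.25, 0.5, 1, 2)
  expect_equal(renkin_crone_mbf(renkin_crone_k1(fs)), fs, tolerance = 1e-6)
  expect_error(renkin_crone_k1(-1), ">= 0")
  expect_error(renkin_crone_mbf(10), "range")
})

test_that("forward 1-TCM matches closed-form solutions per frame", {
  sched <- default_framing_schedule()
  # boxcar input: 1 kBq/mL on [0, 60), else 0, given exactly on the fine grid
  tt_fine <- seq(0.25, 259.75, by = 0.5)
  box <- tac(sched, c(rep(1, 12), rep(0, 28)))
  box$fine <- list(dt = 0.5, values = as.numeric(tt_fine < 60))
  k1 <- 0.3; k2 <- 0.1  # mL/min/g and 1/min
  out <- forward_tissue_tac(box, renkin_crone_mbf(k1), k2 = k2,
                            pv_recovery = 1, spillover = 0)
  # closed form: accumulation then washout, frame-averaged analytically
  l <- k2 / 60
  ct <- function(t) ifelse(t <= 60, (k1 / 60) / l * (1 - exp(-l * t)),
                           (k1 / 60) / l * (1 - exp(-l * 60)) *
                             exp(-l * (t - 60)))
  frame_avg <- vapply(seq_len(40), function(i) {
    integrate(ct, sched$start_s[i], sched$start_s[i] + sched$duration_s[i],
              rel.tol = 1e-10)$value / sched$duration_s[i]
  }, numeric(1))
  expect_lt(max(abs(out$values - frame_avg) / max(frame_avg)), 0.01)

  # mono-exponential input: closed form K1*(e^{-at} - e^{-k2 t})/(k2 - a)
  a <- 0.02  # 1/s
  expo <- tac(sched, rep(0.5, 40))
  expo$fine <- list(dt = 0.5, values = exp(-a * tt_fine))
  expo$values <- tmsflow:::rebin_to_frames(expo$fine$values, sched)
  out2 <- forward_tissue_tac(expo, renkin_crone_mbf(k1), k2 = k2,
                             pv_recovery = 1, spillover = 0)
  ct2 <- function(t) (k1 / 60) * (exp(-a * t) - exp(-l * t)) / (l - a)
  frame_avg2 <- vapply(seq_len(40), function(i) {
    integrate(ct2, sched$start_s[i], sched$start_s[i] + sched$duration_s[i],
              rel.tol = 1e-10)$value / sched$duration_s[i]
  }, numeric(1))
  expect_lt(max(abs(out2$values - frame_avg2) / max(abs(frame_avg2))), 0.01)
})

test_that("degenerate forward cases behave as closed forms dictate", {
  ab <- default_bolus_aif()
  # zero flow, zero spillover: all-zero tissue curve
  z <- forward_tissue_tac(ab, 0, k2 = 0.1, pv_recovery = 1, spillover = 0)
  expect_equal(max(abs(z$values)), 0)
  # k2 = 0: pure accumulation, C_t(end) = K1 * integral of C_a
  acc <- forward_tissue_tac(ab, 1.0, k2 = 0, pv_recovery = 1, spillover = 0)
  k1 <- renkin_crone_k1(1.0)
  expect_equal(acc$fine$values[length(acc$fine$values)],
               (k1 / 60) * frame_window_sum(ab, 0, 260),
               tolerance = 0.01 * (k1 / 60) * frame_window_sum(ab, 0, 260))
})

test_that("flow map: contiguous wedge scar of requested size and bands", {
  grid <- polar_grid()
  fm <- ground_truth_flow_map(grid, scar_frac_lv = 0.26, seed = 3)
  expect_equal(fm$scar_frac_lv, 0.26, tolerance = 0.02)
  comp <- tmsflow:::mask_components(fm$scar_mask, grid$adj)
  expect_equal(max(comp), 1L)
  expect_true(all(fm$mbf[fm$scar_mask] >= 0.15 & fm$mbf[fm$scar_mask] <= 0.35))
  expect_true(all(fm$mbf[fm$stratum == "normal"] >= 0.55))
  # every fine region maps to exactly one segment, all 17 represented
  expect_setequal(unique(grid$segment), 1:17)
  expect_error(ground_truth_flow_map(grid, scar_frac_lv = 0.9), "scar_frac")
})

test_that("simulate_phantom is deterministic and honors the protocol", {
  grid <- small_grid()
  fm <- ground_truth_flow_map(grid, seed = 5)
  spec <- noiseless_spec(fm, rng_seed = 9)
  s1 <- simulate_phantom(spec)
  s2 <- simulate_phantom(spec)
  expect_length(s1, 3L)
  expect_identical(s1[[1]]$tissue, s2[[1]]$tissue)
  expect_identical(s1[[2]]$blood$la_aorta$values, s2[[2]]$blood$la_aorta$values)
  # same flow map across the three scans
  expect_identical(s1[[1]]$truth$mbf, s1[[3]]$truth$mbf)
  # noisy scans differ between scan indices but reproduce under one seed
  specn <- phantom_spec(fm, rng_seed = 9)
  n1 <- simulate_phantom(specn)
  n2 <- simulate_phantom(specn)
  expect_identical(n1[[1]]$tissue, n2[[1]]$tissue)
  expect_false(identical(n1[[1]]$tissue, n1[[2]]$tissue))
})

test_that("noiseless uptake is lowest inside the scar and monotone in flow", {
  grid <- polar_grid()
  fm <- ground_truth_flow_map(grid, scar_frac_lv = 0.26, seed = 21)
  st <- simulate_phantom(noiseless_spec(fm, rng_seed = 2))[[1]]
  late <- st$schedule$start_s >= 140
  uptake <- rowMeans(st$tissue[, late])
  ru <- compute_relative_uptake(uptake)
  expect_true(which.min(ru) %in% which(fm$scar_mask))
  # scar regions sit in the severe-uptake regime at segment level
  seg_ru <- compute_relative_uptake(aggregate_to_segments(grid, uptake))
  seg_cov <- vapply(1:17, function(s) {
    i <- grid$segment == s
    sum(grid$area[i & fm$scar_mask]) / sum(grid$area[i])
  }, numeric(1))
  expect_true(all(seg_ru[seg_cov > 0.9] > 30 & seg_ru[seg_cov > 0.9] < 55))
  # monotone: across strata, mean uptake orders as mean true flow
  expect_lt(mean(uptake[fm$stratum == "scar"]),
            mean(uptake[fm$stratum == "border"]))
  expect_lt(mean(uptake[fm$stratum == "border"]),
            mean(uptake[fm$stratum == "normal"]))
})

test_that("artifact injection modifies studies as specified", {
  grid <- small_grid()
  fm <- ground_truth_flow_map(grid, seed = 6)
  st <- simulate_phantom(noiseless_spec(fm, rng_seed = 3))[[1]]
  # saturation clips the blood maximum at the ceiling (on the fine curve;
  # frame averages then sit at or below it)
  ceil <- 0.8 * max(st$blood$la_aorta$fine$values)
  sat <- inject_artifact(st, "scanner_saturation", list(ceiling_frac = 0.8))
  expect_equal(max(sat$blood$la_aorta$fine$values), ceil, tolerance = 1e-9)
  expect_lte(max(sat$blood$la_aorta$values), ceil + 1e-9)
  # abrupt motion leaves pre-step frames untouched
  mov <- inject_artifact(st, "abrupt_motion",
                         list(t_step_s = 130, shift_sectors = 2))
  pre <- st$schedule$start_s < 130
  expect_identical(mov$tissue[, pre], st$tissue[, pre])
  expect_false(identical(mov$tissue[, !pre], st$tissue[, !pre]))
  # frame-duration corruption touches only the observed durations
  fd <- inject_artifact(st, "inconsistent_frame_duration")
  expect_equal(sum(fd$observed_duration_s != st$schedule$duration_s), 1L)
  expect_error(inject_artifact(st, "not_a_kind"), "unknown artifact")
})
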