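test_that("relative uptake normalizes to the maximum region", {
  expect_equal(compute_relative_uptake(c(2, 1, 4)), c(50, 25, 100))
  expect_equal(compute_relative_uptake(rep(3, 5)), rep(100, 5))
  # a scar at 0.43x the hottest region reads 43 %RU by construction
  expect_equal(compute_relative_uptake(c(0.43, 1) * 7)[1], 43)
  expect_error(compute_relative_uptake(c(0, 0)), "degenerate")
  expect_error(compute_relative_uptake(c(-1, 2)), ">= 0")
})

test_that("rest score follows the clinical bins, monotone in %RU", {
  expect_equal(segment_rest_score(100), 0)
  expect_equal(segment_rest_score(70), 0)
  expect_equal(segment_rest_score(60), 1)
  expect_equal(segment_rest_score(55), 2)
  expect_equal(segment_rest_score(43), 3)
  expect_equal(segment_rest_score(5), 4)
  rus <- seq(0, 100, by = 0.5)
  scores <- vapply(rus, segment_rest_score, numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_error(segment_rest_score(101), "scalar")
})

test_that("ROI identification finds the largest contiguous severe region", {
  grid <- polar_grid()
  ru <- rep(100, grid$n)
  mbf <- rep(0.8, grid$n)
  # uniform map: empty ROI, flagged not raised
  empty <- identify_roi_scar(ru, mbf, grid)
  expect_true(empty$empty)
  expect_equal(empty$roi_size_pct_lv, 0)
  # construct a 26% LV contiguous wedge at 43 %RU
  fm <- ground_truth_flow_map(grid, scar_frac_lv = 0.26, seed = 2)
  ru2 <- ifelse(fm$scar_mask, 43, 100)
  mbf2 <- ifelse(fm$scar_mask, 0.25, 0.8)
  roi <- identify_roi_scar(ru2, mbf2, grid)
  expect_false(roi$empty)
  expect_equal(roi$roi_size_pct_lv, 26, tolerance = 1)
  expect_equal(roi$roi_mean_rmbf, 0.25)
  expect_equal(roi$roi_mean_ru, 43)
  expect_lte(roi$roi_min_rmbf, roi$roi_mean_rmbf)
  # two disjoint defects: the larger one wins, the other is reported
  basal <- which(grid$ring == "basal")
  small <- basal[1:11]  # ~5% LV, contiguous along the ring
  ru3 <- ru2; ru3[small] <- 40
  mbf3 <- mbf2; mbf3[small] <- 0.4
  roi3 <- identify_roi_scar(ru3, mbf3, grid)
  expect_equal(roi3$roi_size_pct_lv, roi$roi_size_pct_lv)
  expect_equal(nrow(roi3$secondary_components), 1L)
  expect_equal(roi3$secondary_components$size_pct_lv, 5, tolerance = 0.5)
})

test_that("AHA adjacency is symmetric and has the documented apex edges", {
  e <- aha_adjacency()
  expect_true(all(e >= 1 & e <= 17))
  apex <- sort(unique(c(e[e[, 1] == 17, 2], e[e[, 2] == 17, 1])))
  expect_equal(apex, 13:16)
  # inferior column: basal 4 - mid 10 - apical 15 are chained
  has_edge <- function(a, b)
    any((e[, 1] == a & e[, 2] == b) | (e[, 1] == b & e[, 2] == a))
  expect_true(has_edge(4, 10))
  expect_true(has_edge(10, 15))
  expect_false(has_edge(1, 4))
})

test_that("segment classification applies the four criteria then contiguity", {
  grid <- polar_grid()
  # construct an inferior defect: segments 4, 10, 15 fully inside, 3 and 9
  # at 30% coverage
  defect <- rep(FALSE, grid$n)
  defect[grid$segment %in% c(4, 10, 15)] <- TRUE
  for (s in c(3, 9)) {
    i <- which(grid$segment == s)
    defect[i[seq_len(ceiling(0.3 * length(i)))]] <- TRUE
  }
  ru <- ifelse(1:17 %in% c(4, 10, 15), 43,
               ifelse(1:17 %in% c(3, 9), 60, 95))
  segs <- segment_table(data.frame(
    segment_id = 1:17,
    rmbf = ifelse(1:17 %in% c(4, 10, 15), 0.25,
                  ifelse(1:17 %in% c(3, 9), 0.5, 0.8)),
    ru_percent = ru,
    rest_score = vapply(ru, segment_rest_score, numeric(1))))
  cl <- classify_segments(segs, defect, grid)
  expect_setequal(cl$seg_scar, c(4, 10, 15))
  expect_setequal(cl$seg_border, c(3, 9))
  expect_length(cl$seg_norm, 12L)
  # the three groups partition the 17 segments
  expect_setequal(c(cl$seg_scar, cl$seg_border, cl$seg_norm), 1:17)
  expect_equal(cl$seg_scar_mean_rmbf, 0.25)
  expect_equal(cl$lowest_segment_rmbf, 0.25)
  # a 40% coverage segment with %RU 60 lands in the border zone
  expect_true(all(cl$coverage[c(3, 9)] < 0.5 & cl$coverage[c(3, 9)] > 0))
})

test_that("tightening any criterion never enlarges Seg-Scar", {
  grid <- polar_grid()
  fm <- partial_coverage_flow_map(grid, 4)
  st <- simulate_phantom(phantom_spec(fm, rng_seed = 44))[[1]]
  est <- estimate_study(st, "retention")
  roi <- identify_roi_scar(est$fine_ru, est$fine_mbf, grid)
  base <- classify_segments(est$segments, roi$roi_mask, grid,
                            seg_scar_criteria())
  for (crit in list(seg_scar_criteria(defect_coverage_threshold = 0.7),
                    seg_scar_criteria(segment_score_min = 3),
                    seg_scar_criteria(ru_max_percent = 45))) {
    tight <- classify_segments(est$segments, roi$roi_mask, grid, crit)
    expect_true(all(tight$seg_scar %in% base$seg_scar))
  }
})

test_that("every classification output partitions and stays contiguous", {
  grid <- polar_grid()
  adj17 <- tmsflow:::adjacency_list(aha_adjacency(), 17L)
  for (i in 1:8) {
    fm <- partial_coverage_flow_map(grid, i)
    st <- simulate_phantom(phantom_spec(fm, rng_seed = 600 + i))[[1]]
    sa <- scar_analysis(estimate_study(st, "retention"), grid)
    expect_setequal(c(sa$seg_scar, sa$seg_border, sa$seg_norm), 1:17)
    if (length(sa$seg_scar) > 1) {
      inmask <- seq_len(17) %in% sa$seg_scar
      expect_equal(max(tmsflow:::mask_components(inmask, adj17)), 1L)
    }
    if (!sa$empty) expect_lte(sa$roi_min_rmbf, sa$roi_mean_rmbf)
  }
})
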