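test_that("default schedule is 28x5s + 12x10s, contiguous, 260 s total", {
  sched <- default_framing_schedule()
  expect_equal(nrow(sched), 40L)
  expect_equal(sched$duration_s, c(rep(5, 28), rep(10, 12)))
  expect_equal(schedule_total_s(sched), 260)
  # contiguity forces frame 29 to start at 140 s with 10 s duration
  expect_equal(sched$start_s[29], 140)
  expect_equal(sched$duration_s[29], 10)
  expect_equal(sched$start_s[-1], head(sched$start_s + sched$duration_s, -1))
})

test_that("framing_schedule rejects invalid grids", {
  expect_error(framing_schedule(c(0, 5), c(5, 0)), "durations")
  expect_error(framing_schedule(c(0, 6), c(5, 5)), "contiguous")
  expect_error(framing_schedule(c(1, 6), c(5, 5)), "start at 0")
})

test_that("tac validates length, finiteness and the negative-value flag", {
  sched <- default_framing_schedule()
  expect_error(tac(sched, rep(1, 39)), "does not match")
  expect_error(tac(sched, c(rep(1, 39), NA)), "finite")
  expect_error(tac(sched, c(-1, rep(1, 39))), "noise_active")
  expect_silent(tac(sched, c(-1, rep(1, 39)), noise_active = TRUE))
})

test_that("frame_window_sum is the rectangle-rule integral on frames", {
  sched <- default_framing_schedule()
  # constant curve: integral over [0, 120) is 120
  expect_equal(frame_window_sum(tac(sched, rep(1, 40)), 0, 120), 120)
  # the first-two-minutes window covers exactly 24 five-second frames
  expect_equal(120 / 5, 24)
  expect_equal(frame_window_sum(tac(sched, c(rep(1, 24), rep(9, 16))),
                                0, 120), 120)
  # curve = 0-based frame index: [0, 10) -> 0*5 + 1*5 = 5 (hand summation)
  expect_equal(frame_window_sum(tac(sched, 0:39), 0, 10), 5)
  # windows must align to frame boundaries; no silent interpolation
  expect_error(frame_window_sum(tac(sched, rep(1, 40)), 0, 17), "aligned")
})

test_that("frame_window_sum is additive over adjacent windows", {
  sched <- default_framing_schedule()
  set.seed(11)
  x <- tac(sched, runif(40, 0, 50))
  for (b in c(60, 120, 140, 200)) {
    expect_equal(frame_window_sum(x, 0, b) + frame_window_sum(x, b, 260),
                 frame_window_sum(x, 0, 260))
  }
})

test_that("TAC JSON round-trip is bit-exact and CSV round-trip is close", {
  sched <- default_framing_schedule()
  set.seed(2)
  x <- tac(sched, runif(40, 0, 123.456), region_label = "sector_7")
  jf <- tempfile(fileext = ".json")
  cf <- tempfile(fileext = ".csv")
  write_tac(x, jf)
  y <- read_tac(jf)
  expect_identical(y$values, x$values)
  expect_identical(y$region_label, x$region_label)
  expect_equal(y$schedule$start_s, sched$start_s)
  write_tac(x, cf)
  z <- read_tac(cf)
  expect_equal(z$values, x$values, tolerance = 1e-6)
  unlink(c(jf, cf))
})

test_that("malformed TAC files produce parse errors naming line and field", {
  cf <- tempfile(fileext = ".csv")
  writeLines(c("start_s,duration_s,value_kBq_per_mL",
               "0,5,1.0", "5,5,oops"), cf)
  expect_error(read_tac(cf), "line 3.*oops")
  writeLines(c("start_s,duration_s,value_kBq_per_mL",
               "0,5,1.0", "5,5"), cf)
  expect_error(read_tac(cf), "line 3")
  # missing a frame row -> schedule no longer matches its own contiguity
  writeLines(c("start_s,duration_s,value_kBq_per_mL",
               "0,5,1.0", "10,5,2.0"), cf)
  expect_error(read_tac(cf), "schedule invalid")
  unlink(cf)
  expect_error(read_tac("no/such/file.json"), "not found")
})

test_that("segment tables validate and round-trip through CSV", {
  df <- data.frame(segment_id = 1:17, rmbf = seq(0.2, 1.0, length.out = 17),
                   ru_percent = seq(40, 100, length.out = 17),
                   rest_score = rep(c(3, 0), c(5, 12)))
  st <- segment_table(df)
  f <- tempfile(fileext = ".csv")
  write_segment_table(st, f)
  st2 <- read_segment_table(f)
  expect_equal(st2$rmbf, st$rmbf, tolerance = 1e-9)
  unlink(f)
  expect_error(segment_table(df[-1, ]), "17")
  df2 <- df; df2$ru_percent[1] <- 101
  expect_error(segment_table(df2), "0, 100")
  df3 <- df; df3$rmbf[3] <- -0.1
  expect_error(segment_table(df3), "rmbf")
})

test_that("reference constants carry the printed protocol values", {
  k <- reference_constants()
  expect_equal(k$pv_recovery, 0.85)
  expect_equal(k$dose_per_kg_MBq, 11.4)
  expect_equal(k$input_window_s, 120)
  expect_equal(k$tms_uptake_threshold_percent, 50)
  expect_equal(nrow(k$literature_rows), 12L)
})
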