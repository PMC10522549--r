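# Fine-grid (sub-second) curve machinery shared by the simulator and the
# kinetic estimators. Frame-average TACs are lifted to a uniform fine grid
# (midpoint samples), convolved there, and re-binned to frames; convolving
# directly on the mixed 5/10-s frame grid would be ill-defined.

FINE_DT <- 0.5  # seconds

fine_times <- function(total_s, dt = FINE_DT) {
  seq(dt / 2, total_s - dt / 2, by = dt)
}

#' Fine-grid representation of a TAC
#'
#' Returns midpoint samples of the curve on a uniform `dt` grid. If the TAC
#' carries an exact fine representation from the simulator it is used;
#' otherwise frame-average values are linearly interpolated at frame
#' midpoints (constant extrapolation at the ends).
#'
#' @param x A [tac()].
#' @param dt Fine grid step in seconds.
#' @return List with `t` and `values`.
#' @keywords internal
tac_fine <- function(x, dt = FINE_DT) {
  total <- schedule_total_s(x$schedule)
  tt <- fine_times(total, dt)
  if (!is.null(x$fine) && isTRUE(all.equal(x$fine$dt, dt)))
    return(list(t = tt, values = x$fine$values))
  v <- stats::approx(frame_mids(x$schedule), x$values, xout = tt,
                     rule = 2)$y
  list(t = tt, values = v)
}

# Average fine-grid samples within each frame. Frame boundaries must be
# multiples of dt (true for the 5/10-s default schedule and dt = 0.5).
rebin_to_frames <- function(values_fine, schedule, dt = FINE_DT) {
  idx <- findInterval(fine_times(schedule_total_s(schedule), dt) ,
                      schedule$start_s)
  as.numeric(tapply(values_fine, idx, mean))
}

# y(t) = (C ** exp(-lambda t))(t) on the fine grid, trapezoidal update:
# y_i = e*y_{i-1} + (dt/2)*(C_i + e*C_{i-1}), e = exp(-lambda*dt).
conv_exp_fine <- function(values_fine, lambda_per_s, dt = FINE_DT) {
  if (lambda_per_s < 0) stop("decay rate must be >= 0")
  e <- exp(-lambda_per_s * dt)
  cprev <- c(0, values_fine[-length(values_fine)])
  z <- (dt / 2) * (values_fine + e * cprev)
  as.numeric(stats::filter(z, e, method = "recursive"))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h)
}
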