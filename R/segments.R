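#' Validate a 17-segment result table
#'
#' The standard AHA 17-segment model: exactly 17 unique segment ids 1..17,
#' resting MBF >= 0 (mL/min/g), percent relative uptake in [0, 100], and an
#' optional 0-4 per-segment rest score.
#'
#' @param df Data frame with columns `segment_id`, `rmbf`, `ru_percent` and
#'   optionally `rest_score`.
#' @return The validated data frame (sorted by `segment_id`) with class
#'   `segment_table`.
#' @export
segment_table <- function(df) {
  need <- c("segment_id", "rmbf", "ru_percent")
  if (!all(need %in% names(df)))
    stop(sprintf("segment table must have columns %s",
                 paste(need, collapse = ", ")))
  if (nrow(df) != 17L || !setequal(df$segment_id, 1:17))
    stop("segment table must contain exactly the 17 AHA segments (ids 1..17)")
  if (any(!is.finite(df$rmbf)) || any(df$rmbf < 0))
    stop("rmbf must be finite and >= 0")
  if (any(!is.finite(df$ru_percent)) ||
      any(df$ru_percent < 0) || any(df$ru_percent > 100))
    stop("ru_percent must lie in [0, 100]")
  if ("rest_score" %in% names(df)) {
    if (any(!df$rest_score %in% 0:4))
      stop("rest_score must be an integer in 0..4")
  }
  df <- df[order(df$segment_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("segment_table", "data.frame")
  df
}

# Angular spans (degrees, half-open [lo, hi)) of the AHA segments, anterior
# wall centred at 90 deg. Basal/mid walls span 60 deg, apical quadrants 90.
aha_spans <- function() {
  basal_mid <- rbind(
    c(60, 120),   # anterior
    c(120, 180),  # anteroseptal / septal
    c(180, 240),  # inferoseptal
    c(240, 300),  # inferior
    c(300, 360),  # inferolateral
    c(0, 60))     # anterolateral
  apical <- rbind(
    c(45, 135),   # 13 anterior
    c(135, 225),  # 14 septal
    c(225, 315),  # 15 inferior
    c(315, 405))  # 16 lateral (wraps)
  list(basal = basal_mid, mid = basal_mid, apical = apical)
}

angle_in_span <- function(theta, lo, hi) {
  t2 <- theta %% 360
  (t2 >= lo & t2 < hi) | (t2 + 360 >= lo & t2 + 360 < hi)
}

#' AHA 17-segment adjacency graph
#'
#' Fixed edge list defining which segments touch on the polar map: ring
#' neighbours within the basal (1-6), mid (7-12) and apical (13-16) rings,
#' radial neighbours between rings (by angular overlap for mid-apical), and
#' the apex (17) adjacent to all four apical segments.
#'
#' @return Two-column integer matrix of undirected edges.
#' @export
aha_adjacency <- function() {
  e <- list()
  ring6 <- function(off) cbind(off + 1:6, off + c(2:6, 1))
  e$basal <- ring6(0)
  e$mid <- ring6(6)
  e$apical <- cbind(13:16, c(14, 15, 16, 13))
  e$basal_mid <- cbind(1:6, 7:12)
  # mid-apical edges by angular overlap of the spans above
  sp <- aha_spans()
  ma <- NULL
  for (m in 1:6) {
    for (a in 1:4) {
      lo1 <- sp$mid[m, 1]; hi1 <- sp$mid[m, 2]
      lo2 <- sp$apical[a, 1]; hi2 <- sp$apical[a, 2]
      ivs <- rbind(c(lo2, hi2), c(lo2 - 360, hi2 - 360))
      if (any(pmin(hi1, ivs[, 2]) - pmax(lo1, ivs[, 1]) > 1e-9))
        ma <- rbind(ma, c(6 + m, 12 + a))
    }
  }
  e$mid_apical <- ma
  e$apex <- cbind(13:16, 17)
  edges <- do.call(rbind, e)
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  edges
}

adjacency_list <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

#' Fine polar sampling grid of the left ventricle
#'
#' The fine grid on which ROI-level analysis operates: three angular rings
#' (basal, mid, apical) of `n_sectors` sectors each, plus a single apex-cap
#' region. Every region maps to exactly one AHA segment; the apex cap carries
#' segment 17. Region areas are equal per sector, with the apex cap given the
#' area of `apex_area_sectors` sectors.
#'
#' @param n_sectors Sectors per ring; must be a multiple of 24 so that the
#'   6-fold basal/mid and 4-fold apical segment boundaries fall on sector
#'   boundaries. Default 72.
#' @param apex_area_sectors Area of the apex cap in sector units. Default 4.
#' @return An object of class `polar_grid` with components `n` (number of
#'   regions), `ring`, `theta` (sector centre angle, degrees), `segment`
#'   (AHA id per region), `area` (relative area per region) and `adj`
#'   (adjacency list).
#' @export
polar_grid <- function(n_sectors = 72, apex_area_sectors = 4) {
  if (n_sectors %% 24 != 0)
    stop("n_sectors must be a multiple of 24")
  rings <- c("basal", "mid", "apical")
  n <- 3L * n_sectors + 1L
  ring <- c(rep(rings, each = n_sectors), "apex")
  step <- 360 / n_sectors
  theta <- c(rep((seq_len(n_sectors) - 0.5) * step, 3), NA_real_)
  sp <- aha_spans()
  seg <- integer(n)
  for (r in 1:3) {
    offs <- c(0L, 6L, 12L)[r]
    spans <- sp[[r]]
    for (k in seq_len(nrow(spans))) {
      idx <- (r - 1L) * n_sectors +
        which(angle_in_span(theta[(r - 1L) * n_sectors + seq_len(n_sectors)],
                            spans[k, 1], spans[k, 2]))
      seg[idx] <- offs + k
    }
  }
  seg[n] <- 17L
  area <- c(rep(1, 3L * n_sectors), apex_area_sectors)

  # adjacency: angular neighbours within ring (wrapping), radial neighbour at
  # the same angle in the adjacent ring, apex cap adjacent to apical ring
  edges <- NULL
  for (r in 1:3) {
    off <- (r - 1L) * n_sectors
    i <- off + seq_len(n_sectors)
    edges <- rbind(edges, cbind(i, off + c(seq_len(n_sectors)[-1L], 1L)))
    if (r < 3) edges <- rbind(edges, cbind(i, i + n_sectors))
  }
  edges <- rbind(edges, cbind(2L * n_sectors + seq_len(n_sectors), n))
  structure(list(n = n, n_sectors = as.integer(n_sectors), ring = ring,
                 theta = theta, segment = seg, area = area,
                 adj = adjacency_list(edges, n)),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("polar_grid: %d regions (%d sectors x 3 rings + apex cap)\n",
              x$n, x$n_sectors))
  invisible(x)
}

#' Connected components of a region mask on a grid adjacency
#'
#' @param mask Logical vector over grid regions.
#' @param adj Adjacency list.
#' @return Integer vector: component label per region (0 outside the mask).
#' @keywords internal
mask_components <- function(mask, adj) {
  comp <- integer(length(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (mask[w] && comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Area-weighted aggregation of a fine-grid map to 17 segments
#'
#' @param grid A [polar_grid()].
#' @param values Numeric vector over grid regions.
#' @return Numeric vector of length 17 (segment order 1..17).
#' @export
aggregate_to_segments <- function(grid, values) {
  stopifnot(inherits(grid, "polar_grid"), length(values) == grid$n)
  vapply(1:17, function(s) {
    i <- grid$segment == s
    sum(values[i] * grid$area[i]) / sum(grid$area[i])
  }, numeric(1))
}
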