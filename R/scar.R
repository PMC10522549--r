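#' Percent relative uptake
#'
#' Normalizes a nonnegative uptake map to its maximum region:
#' `%RU = 100 * value / max(value)`, so the hottest region is 100.
#'
#' @param values Nonnegative uptake values, at least one > 0.
#' @return Vector of %RU in [0, 100].
#' @examples
#' compute_relative_uptake(c(2, 1, 4))  # 50 25 100
#' @export
compute_relative_uptake <- function(values) {
  if (any(values < 0)) stop("uptake values must be >= 0")
  m <- max(values)
  if (m <= 0) stop("degenerate uptake map: all values are zero")
  pmin(100 * values / m, 100)  # guard the maximum against rounding overshoot
}

#' Segment rest score from percent relative uptake
#'
#' Standard 5-point clinical severity scoring, monotone non-increasing in
#' %RU: `>= 70 -> 0` (normal), `60-69 -> 1` (mildly reduced),
#' `50-59 -> 2` (moderately reduced), `30-49 -> 3` (severely reduced),
#' `< 30 -> 4` (absent uptake). Bin edges are exposed so laboratories can
#' re-map them.
#'
#' @param ru_percent %RU in [0, 100] (scalar).
#' @param bins Decreasing vector of lower bin edges for scores 0..3.
#' @return Integer score 0-4.
#' @export
segment_rest_score <- function(ru_percent, bins = c(70, 60, 50, 30)) {
  if (length(ru_percent) != 1L || is.na(ru_percent) ||
      ru_percent < 0 || ru_percent > 100)
    stop("ru_percent must be a scalar in [0, 100]")
  if (ru_percent >= bins[1]) return(0)
  if (ru_percent >= bins[2]) return(1)
  if (ru_percent >= bins[3]) return(2)
  if (ru_percent >= bins[4]) return(3)
  4
}

#' Segmental scar criteria
#'
#' The four criteria a segment must meet to count as scar in the segmental
#' (Seg-Scar) analysis: membership in a contiguous group, defect coverage of
#' more than half the segment, rest score of at least 2, and %RU below 65%
#' of maximum.
#'
#' @param require_contiguity Keep only the largest contiguous candidate
#'   group on the AHA adjacency graph.
#' @param defect_coverage_threshold Minimum fraction of segment area inside
#'   the defect (strict >; default 0.50).
#' @param segment_score_min Minimum rest score (>=; default 2).
#' @param ru_max_percent Maximum %RU (strict <; default 65).
#' @return An object of class `seg_scar_criteria`.
#' @export
seg_scar_criteria <- function(require_contiguity = TRUE,
                              defect_coverage_threshold = 0.50,
                              segment_score_min = 2,
                              ru_max_percent = 65) {
  if (defect_coverage_threshold <= 0 || segment_score_min <= 0 ||
      ru_max_percent <= 0)
    stop("criteria thresholds must be positive")
  structure(list(require_contiguity = isTRUE(require_contiguity),
                 defect_coverage_threshold = defect_coverage_threshold,
                 segment_score_min = segment_score_min,
                 ru_max_percent = ru_max_percent),
            class = "seg_scar_criteria")
}

#' Identify the transmural-scar region of interest on the fine grid
#'
#' Thresholds the fine %RU map at `uptake_threshold` (<=, the transmural
#' scar definition), takes the largest contiguous component on the grid
#' adjacency (ties broken by lower mean %RU), and summarizes it: size as
#' %LV (area fraction), mean and minimum rMBF inside, and mean %RU inside.
#' Secondary components are reported separately. An empty result (no region
#' at or below threshold) is flagged, not an error.
#'
#' @param fine_ru Fine-grid %RU map (from [compute_relative_uptake()]).
#' @param fine_mbf Fine-grid rMBF map (mL/min/g), same grid.
#' @param grid The [polar_grid()].
#' @param uptake_threshold %RU threshold defining transmural scar
#'   (default 50).
#' @return List with `roi_mask`, `empty`, `roi_size_pct_lv`,
#'   `roi_mean_rmbf`, `roi_min_rmbf`, `roi_mean_ru` and
#'   `secondary_components` (a data frame).
#' @export
identify_roi_scar <- function(fine_ru, fine_mbf, grid, uptake_threshold = 50) {
  stopifnot(inherits(grid, "polar_grid"),
            length(fine_ru) == grid$n, length(fine_mbf) == grid$n)
  below <- fine_ru <= uptake_threshold
  if (!any(below)) {
    return(list(roi_mask = below, empty = TRUE,
                roi_size_pct_lv = 0, roi_mean_rmbf = NA_real_,
                roi_min_rmbf = NA_real_, roi_mean_ru = NA_real_,
                secondary_components = data.frame()))
  }
  comp <- mask_components(below, grid$adj)
  stats_comp <- do.call(rbind, lapply(seq_len(max(comp)), function(k) {
    i <- comp == k
    data.frame(component = k,
               size_pct_lv = 100 * sum(grid$area[i]) / sum(grid$area),
               mean_rmbf = sum(fine_mbf[i] * grid$area[i]) / sum(grid$area[i]),
               min_rmbf = min(fine_mbf[i]),
               mean_ru = sum(fine_ru[i] * grid$area[i]) / sum(grid$area[i]))
  }))
  ord <- order(-stats_comp$size_pct_lv, stats_comp$mean_ru)
  main <- stats_comp[ord[1L], ]
  list(roi_mask = comp == main$component, empty = FALSE,
       roi_size_pct_lv = main$size_pct_lv,
       roi_mean_rmbf = main$mean_rmbf,
       roi_min_rmbf = main$min_rmbf,
       roi_mean_ru = main$mean_ru,
       secondary_components = stats_comp[ord[-1L], , drop = FALSE])
}

#' Classify the 17 segments as Seg-Scar, Seg-Border, Seg-Norm
#'
#' Applies the four segmental scar criteria to a segment table and the
#' fine-grid defect mask: candidate segments must have defect coverage
#' above the threshold, rest score at or above the minimum and %RU below
#' the maximum; the Seg-Scar set is the maximal contiguous candidate group
#' on the AHA adjacency graph (criteria first, then contiguity). Segments
#' intersecting the defect but failing a criterion (or outside the chosen
#' contiguous group) form the Seg-Border zone; all remaining segments are
#' Seg-Norm. The three groups always partition the 17 segments.
#'
#' @param seg_table A [segment_table()] with a `rest_score` column.
#' @param fine_defect_mask Logical fine-grid mask of the contiguous
#'   perfusion defect (typically the ROI-Scar mask).
#' @param grid The [polar_grid()].
#' @param criteria A [seg_scar_criteria()].
#' @return List with `seg_scar`, `seg_border`, `seg_norm` (segment ids),
#'   per-group mean rMBF, `lowest_segment_rmbf` (minimum over Seg-Scar),
#'   `coverage` (per-segment defect coverage) and `empty_seg_scar` flag.
#' @export
classify_segments <- function(seg_table, fine_defect_mask, grid,
                              criteria = seg_scar_criteria()) {
  seg_table <- segment_table(seg_table)
  stopifnot(inherits(grid, "polar_grid"),
            length(fine_defect_mask) == grid$n)
  if (!"rest_score" %in% names(seg_table))
    stop("seg_table must carry a rest_score column")
  coverage <- vapply(1:17, function(s) {
    i <- grid$segment == s
    sum(grid$area[i & fine_defect_mask]) / sum(grid$area[i])
  }, numeric(1))
  cand <- coverage > criteria$defect_coverage_threshold &
    seg_table$rest_score >= criteria$segment_score_min &
    seg_table$ru_percent < criteria$ru_max_percent
  scar_ids <- integer(0)
  if (any(cand)) {
    if (criteria$require_contiguity) {
      adj17 <- adjacency_list(aha_adjacency(), 17L)
      comp <- mask_components(cand, adj17)
      sizes <- tabulate(comp[comp > 0])
      keep <- which(sizes == max(sizes))
      if (length(keep) > 1L) {
        # tie-break: lower mean rMBF (the more severe group)
        means <- vapply(keep, function(k)
          mean(seg_table$rmbf[comp == k]), numeric(1))
        keep <- keep[which.min(means)]
      }
      scar_ids <- which(comp == keep)
    } else scar_ids <- which(cand)
  }
  intersecting <- which(coverage > 0)
  border_ids <- setdiff(intersecting, scar_ids)
  norm_ids <- setdiff(1:17, union(scar_ids, border_ids))
  grp_mean <- function(ids)
    if (length(ids)) mean(seg_table$rmbf[ids]) else NA_real_
  list(seg_scar = scar_ids, seg_border = border_ids, seg_norm = norm_ids,
       seg_scar_mean_rmbf = grp_mean(scar_ids),
       seg_border_mean_rmbf = grp_mean(border_ids),
       seg_norm_mean_rmbf = grp_mean(norm_ids),
       lowest_segment_rmbf = if (length(scar_ids))
         min(seg_table$rmbf[scar_ids]) else NA_real_,
       coverage = coverage,
       empty_seg_scar = length(scar_ids) == 0L && any(fine_defect_mask))
}

#' Full scar analysis of one estimated study
#'
#' Runs the fine-grid ROI-Scar identification on the study's estimated
#' uptake and flow maps, then the segmental classification against the
#' identified defect, and assembles the combined summary.
#'
#' @param est A `study_estimate` from [estimate_study()].
#' @param grid The [polar_grid()] of the study.
#' @param criteria A [seg_scar_criteria()].
#' @param uptake_threshold %RU threshold of the ROI (default 50).
#' @return An object of class `scar_analysis`: the ROI fields, the
#'   segmental fields and `whole_heart_rmbf`.
#' @export
scar_analysis <- function(est, grid, criteria = seg_scar_criteria(),
                          uptake_threshold = 50) {
  stopifnot(inherits(est, "study_estimate"))
  roi <- identify_roi_scar(est$fine_ru, est$fine_mbf, grid, uptake_threshold)
  seg <- classify_segments(est$segments, roi$roi_mask, grid, criteria)
  structure(c(roi[c("roi_mask", "empty", "roi_size_pct_lv", "roi_mean_rmbf",
                    "roi_min_rmbf", "roi_mean_ru", "secondary_components")],
              seg,
              list(whole_heart_rmbf = est$whole_heart_mbf,
                   segments = est$segments)),
            class = "scar_analysis")
}

#' @export
print.scar_analysis <- function(x, ...) {
  if (x$empty) {
    cat("scar_analysis: no region at or below the uptake threshold\n")
  } else {
    cat(sprintf(
      paste0("scar_analysis: ROI %.1f%% LV, mean rMBF %.3f (min %.3f), ",
             "%%RU %.1f\n  Seg-Scar {%s} mean %.3f | Seg-Border {%s} | ",
             "whole heart %.3f\n"),
      x$roi_size_pct_lv, x$roi_mean_rmbf, x$roi_min_rmbf, x$roi_mean_ru,
      paste(x$seg_scar, collapse = ","), x$seg_scar_mean_rmbf,
      paste(x$seg_border, collapse = ","), x$whole_heart_rmbf))
  }
  invisible(x)
}
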