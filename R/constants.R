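#' Packaged reference constants
#'
#' Versioned constants used across the pipeline: the literature-derived
#' low-flow accuracy gates for transmural scar (ROI 0.39, segmental
#' 0.44 mL/min/g), the partial-volume recovery coefficient (0.85), the
#' weight-based Rb-82 dose (11.4 MBq/kg), the retention-model arterial input
#' window (first 120 s), the transmural-scar uptake threshold (<= 50 %RU of
#' maximum), and the literature summary table of resting MBF in transmural
#' infarct from which the gates derive.
#'
#' @param path Optional path to an alternative JSON constants file with the
#'   same schema; defaults to the packaged file.
#' @return A list of constants; `$literature_rows` is a data frame.
#' @examples
#' k <- reference_constants()
#' k$roi_gate_ml_min_g
#' @export
reference_constants <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_constants.json",
                        package = "tmsflow", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$literature_rows <- as.data.frame(obj$literature_rows)
  obj
}

#' Derive the scar low-flow gates from the literature table
#'
#' Each literature study reports mean +/- SD resting MBF in transmural scar;
#' its upper bound is mean + 1 SD. The gate for a measurement mode (`"roi"`
#' or `"segmental"`) is the maximum such bound over the studies that used
#' that mode, i.e. the highest value still compatible with transmural scar
#' in any reference study.
#'
#' @param mode `"roi"` or `"segmental"`.
#' @param constants Output of [reference_constants()].
#' @return Scalar gate in mL/min/g (0.39 for ROI, 0.44 for segmental with the
#'   packaged table).
#' @export
derive_gate <- function(mode = c("roi", "segmental"),
                        constants = reference_constants()) {
  mode <- match.arg(mode)
  rows <- constants$literature_rows
  rows <- rows[rows$method == mode & !is.na(rows$mean_rmbf), , drop = FALSE]
  if (!nrow(rows)) stop(sprintf("no literature rows with method '%s'", mode))
  max(rows$mean_rmbf + rows$sd_rmbf)
}
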