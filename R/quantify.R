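#' Geometric mean of anterior/posterior planar counts
#'
#' Adds a `gm_counts` column, the elementwise geometric mean
#' \eqn{\sqrt{anterior \times posterior}} of the two conjugate planar
#' views. The geometric mean reduces the depth dependence of planar
#' quantification. A zero count in either view (target lost on one view)
#' yields a zero geometric mean and a warning.
#'
#' If a `scan_speed_cm_min` column is present, counts are first normalised
#' to the speed of the first scan (count rate is inversely proportional to
#' sweep speed); with the study design's constant acquisition speed this is
#' a no-op.
#'
#' @param data Data frame with `time_h`, `anterior_counts`,
#'   `posterior_counts` (equal length, counts >= 0, times strictly
#'   increasing) and optionally `scan_speed_cm_min`.
#' @return `data` with a `gm_counts` column appended.
#' @export
#' @examples
#' geometric_mean_series(tibble::tibble(
#'   time_h = c(0.5, 4), anterior_counts = c(4, 100), posterior_counts = c(9, 100)
#' ))
geometric_mean_series <- function(data) {
  data <- as_tibble(data)
  needed <- c("time_h", "anterior_counts", "posterior_counts")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` must contain columns: ", paste(missing_cols, collapse = ", ")))
  }
  ant <- data$anterior_counts
  post <- data$posterior_counts
  if (any(ant < 0) || any(post < 0)) abort("Counts must be non-negative.")
  if (is.unsorted(data$time_h, strictly = TRUE)) abort("`time_h` must be strictly increasing.")
  if ("scan_speed_cm_min" %in% names(data)) {
    sp <- data$scan_speed_cm_min
    if (any(!is.finite(sp)) || any(sp <= 0)) abort("`scan_speed_cm_min` must be positive.")
    ant <- ant * sp / sp[1]
    post <- post * sp / sp[1]
  }
  if (any(ant == 0 | post == 0)) {
    warn("Zero counts in at least one view; geometric mean is 0 there (target lost on planar imaging).")
  }
  data$gm_counts <- sqrt(ant * post)
  data
}

#' Anchor a planar count series to a quantitative SPECT activity
#'
#' Converts geometric-mean counts into absolute activities by proportional
#' scaling to a single calibrated SPECT-derived activity: \eqn{A(t_i) =
#' GM(t_i) \times A_{SPECT} / GM(t_{anchor})}. At the anchor time the
#' output equals the SPECT activity exactly; the shape of the planar series
#' is preserved (the scale of the counts cancels).
#'
#' @param data Data frame with `time_h` and `gm_counts` (e.g. from
#'   [geometric_mean_series()]).
#' @param anchor_activity_mbq Calibrated activity (MBq, >= 0) at the anchor
#'   time.
#' @param anchor_time_h Anchor time (hours); must equal one of the sample
#'   times. Default 24, the study design's SPECT time point.
#' @return Tibble with `time_h` and `activity_mbq` — a TAC ready for
#'   [fit_tac()].
#' @export
#' @examples
#' gm <- tibble::tibble(time_h = c(0.5, 4, 24, 72),
#'                      gm_counts = c(1000, 800, 500, 200))
#' anchor_to_spect(gm, anchor_activity_mbq = 250)
anchor_to_spect <- function(data, anchor_activity_mbq, anchor_time_h = 24) {
  data <- as_tibble(data)
  if (!all(c("time_h", "gm_counts") %in% names(data))) {
    abort("`data` must contain columns time_h and gm_counts.")
  }
  if (!is.numeric(anchor_activity_mbq) || length(anchor_activity_mbq) != 1L ||
      anchor_activity_mbq < 0) {
    abort("`anchor_activity_mbq` must be a single non-negative number.")
  }
  i <- which(abs(data$time_h - anchor_time_h) < 1e-9)
  if (length(i) != 1L) abort("`anchor_time_h` must equal exactly one of the sample times.")
  gm_anchor <- data$gm_counts[i]
  if (gm_anchor <= 0) {
    abort("Geometric-mean counts at the anchor time are zero; proportional scaling is impossible.")
  }
  tibble(
    time_h = data$time_h,
    activity_mbq = data$gm_counts * anchor_activity_mbq / gm_anchor
  )
}

#' Fraction of total red marrow in a humerus reference volume
#'
#' A small spherical VOI in the proximal humerus stands in for the red
#' marrow; its activity must be scaled up to total-marrow activity by the
#' fraction of marrow it represents. Reference anatomy: 2.3% of the total
#' red marrow lies in the upper half of the humerus, whose reference volume
#' is 180 ml. Two readings of the scaling arithmetic are supported:
#'
#' * `"half_volume"` (default): the 2.3% is spread over half the reference
#'   volume, fraction `= upper_half_fraction * voi / (reference / 2)` —
#'   about 0.1% for a 4.2 ml VOI.
#' * `"full_volume"`: spread over the whole reference volume, fraction
#'   `= upper_half_fraction * voi / reference` — about 0.05%.
#'
#' @param voi_volume_ml VOI volume, default 4.2 ml (2 cm sphere).
#' @param reference_volume_ml Humerus reference volume, default 180 ml.
#' @param upper_half_fraction Marrow fraction in the upper half of the
#'   humerus, default 0.023.
#' @param interpretation `"half_volume"` or `"full_volume"`.
#' @return One-row tibble: `fraction`, `interpretation`.
#' @export
#' @examples
#' red_marrow_fraction()
red_marrow_fraction <- function(voi_volume_ml = 4.2,
                                reference_volume_ml = 180,
                                upper_half_fraction = 0.023,
                                interpretation = c("half_volume", "full_volume")) {
  interpretation <- match.arg(interpretation)
  if (voi_volume_ml <= 0 || reference_volume_ml <= 0) abort("Volumes must be positive.")
  if (upper_half_fraction <= 0 || upper_half_fraction >= 1) {
    abort("`upper_half_fraction` must lie in (0, 1).")
  }
  if (voi_volume_ml > reference_volume_ml) {
    abort("The VOI cannot be larger than the reference volume.")
  }
  denom <- if (interpretation == "half_volume") reference_volume_ml / 2 else reference_volume_ml
  tibble(fraction = upper_half_fraction * voi_volume_ml / denom,
         interpretation = interpretation)
}
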