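# Closed-form assay computations: 2^-ddCt relative expression, knockdown
# percentage, xenograft tumor volume, and IHC positivity scoring.

#' Relative expression by the 2^-ddCt method
#'
#' Per condition, dCt = mean(Ct_target) - mean(Ct_control); the
#' double-normalized ddCt subtracts the calibrator condition's dCt, and
#' the relative expression is 2^-ddCt.
#'
#' @param ct data.frame with columns `condition`, `ct_target`,
#'   `ct_control` (endogenous control, e.g. GAPDH), one row per well.
#' @param condition condition to quantify.
#' @param calibrator reference condition (relative expression 1).
#' @return scalar fold change (2^-ddCt).
#' @export
ddct_fold_change <- function(ct, condition, calibrator) {
  assert_that(all(c("condition", "ct_target", "ct_control") %in% names(ct)),
              "ct needs columns condition, ct_target, ct_control")
  assert_that(all(is.finite(ct$ct_target)) && all(is.finite(ct$ct_control))
              && all(ct$ct_target > 0) && all(ct$ct_control > 0),
              "Ct values must be finite and positive")
  assert_that(condition %in% ct$condition,
              "condition '%s' absent from Ct records", condition)
  assert_that(calibrator %in% ct$condition,
              "calibrator condition '%s' absent from Ct records",
              calibrator)
  dct <- function(cond) {
    rows <- ct$condition == cond
    mean(ct$ct_target[rows]) - mean(ct$ct_control[rows])
  }
  2^-(dct(condition) - dct(calibrator))
}

#' Knockdown percentage from a fold change
#'
#' `(1 - fold_change) * 100`, floored at 0: a fold change of 0.075
#' corresponds to a 92.5% knockdown.
#'
#' @param fold_change relative expression versus control (>= 0).
#' @return percentage in \[0, 100\].
#' @export
knockdown_percent <- function(fold_change) {
  assert_that(all(fold_change >= 0), "fold change must be >= 0")
  pmax(0, (1 - fold_change) * 100)
}

#' Xenograft tumor volume
#'
#' Ellipsoid approximation from caliper measurements:
#' `volume = pi/6 * length * width * height` (mm^3).
#'
#' @param length,width,height tumor dimensions in mm (> 0).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(length, width, height) {
  assert_that(all(length > 0) && all(width > 0) && all(height > 0),
              "all dimensions must be positive")
  pi / 6 * length * width * height
}

#' Immunohistochemistry positivity score
#'
#' Three-tier scoring of the percentage of positively stained cells:
#' score 1 for < 1% (absent/low), score 2 for 1-20% inclusive (medium),
#' score 3 for > 20% (high).
#'
#' @param percent_positive percentage of positive cells in \[0, 100\].
#' @return integer score in `{1, 2, 3}`.
#' @export
ihc_score <- function(percent_positive) {
  assert_that(all(is.finite(percent_positive)) &&
                all(percent_positive >= 0 & percent_positive <= 100),
              "percent_positive must lie in [0, 100]")
  ifelse(percent_positive < 1, 1L,
         ifelse(percent_positive <= 20, 2L, 3L))
}
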