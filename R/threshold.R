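## Threshold-based baseline segmenter: the tumor mask is everything at or
## above a percentage of the maximum reconstructed value inside the breast
## interior.  Sweeping the percentage exposes the sensitivity/specificity
## trade-off that motivates the statistically terminated clustering approach.

#' Threshold-based tumor segmentation
#'
#' Marks the region-of-interest elements whose value is at least
#' `percent / 100` of the maximum value inside the ROI.  The comparison is
#' `>=`, so `percent = 100` returns exactly the argmax elements.
#'
#' @param values numeric matrix, one component image.
#' @param roi binary region-of-interest mask (nonempty).
#' @param percent threshold percentage in (0, 100].
#' @return logical matrix (subset of `roi`).
#' @export
threshold_segment <- function(values, roi, percent) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  stop_if_not_mask(roi, "roi")
  check_same_shape(values, roi, "'values' and 'roi'")
  roi <- as_mask(roi)
  if (!any(roi)) stop("ROI mask is empty", call. = FALSE)
  if (!is.numeric(percent) || length(percent) != 1L || percent <= 0 ||
      percent > 100)
    stop("'percent' must lie in (0, 100]", call. = FALSE)
  cut <- (percent / 100) * max(values[roi])
  roi & values >= cut
}

#' Metric sweep over threshold percentages
#'
#' Applies [threshold_segment] at each percentage and scores the resulting
#' tumor mask against a reference tumor mask, producing one row per
#' percentage with the ratio detected, artefact rejection, Dice coefficient
#' and average Hausdorff distance.  Because the masks are nested (a lower
#' percentage can only add elements), RD is nondecreasing and AR
#' nonincreasing as the percentage decreases.
#'
#' @param values numeric matrix, one component image.
#' @param roi binary region-of-interest mask.
#' @param percents numeric vector of percentages in (0, 100]
#'   (default `c(95, 90, 85, 80)`).
#' @param ref_tumor binary reference tumor mask (nonempty).
#' @param spacing_mm pixel spacing in millimetres.
#' @return data frame with columns `percent`, `rd`, `ar`, `dice`,
#'   `hausdorff_mm` (`NA` when the thresholded mask is empty).
#' @export
threshold_sweep <- function(values, roi, percents = c(95, 90, 85, 80),
                            ref_tumor, spacing_mm = 1) {
  stop_if_not_mask(ref_tumor, "ref_tumor")
  if (!any(as_mask(ref_tumor)))
    stop("'ref_tumor' must be nonempty", call. = FALSE)
  do.call(rbind, lapply(percents, function(p) {
    m <- threshold_segment(values, roi, p)
    data.frame(percent = p,
               rd = ratio_detected(ref_tumor, m),
               ar = artefact_rejection(ref_tumor, m),
               dice = dice(ref_tumor, m),
               hausdorff_mm = if (any(m))
                 hausdorff_masks(ref_tumor, m, spacing_mm) else NA_real_)
  }))
}
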