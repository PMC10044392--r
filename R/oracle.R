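#' Thresholds for the simulated mask-validation oracle
#'
#' The three acceptance criteria used by clinical reviewers are qualitative:
#' (i) the mask must cover the entire wound area; (ii) it must cover only the
#' wound, with no holes or spurious parts; (iii) its shape must follow the
#' correct wound boundaries. The simulated oracle operationalises them with
#' quantitative thresholds against a reference mask. Every threshold is a
#' package decision, chosen so that a perfect mask always passes and each
#' [corrupt_mask()] mode at severity 0.3 or above fails its targeted
#' criterion.
#'
#' @param min_coverage_recall minimum recall for criterion i. Default 0.90.
#' @param min_precision minimum precision for criterion ii. Default 0.90.
#' @param max_hole_area_fraction maximum enclosed-background (hole) area as a
#'   fraction of the mask area, criterion ii. Default 0.01.
#' @param max_spurious_components maximum number of foreground components
#'   beyond the largest, criterion ii. Default 0.
#' @param max_mean_boundary_distance maximum symmetric mean boundary distance
#'   between predicted and reference contours, as a fraction of the image
#'   diagonal, criterion iii. Default 0.02.
#' @return A list of class `validation_thresholds`.
#' @export
validation_thresholds <- function(min_coverage_recall = 0.90,
                                  min_precision = 0.90,
                                  max_hole_area_fraction = 0.01,
                                  max_spurious_components = 0,
                                  max_mean_boundary_distance = 0.02) {
  fr <- c(min_coverage_recall, min_precision)
  if (any(fr <= 0) || any(fr > 1))
    abort_wa("recall/precision thresholds must be in (0, 1]")
  if (max_hole_area_fraction < 0 || max_spurious_components < 0 ||
      max_mean_boundary_distance < 0)
    abort_wa("thresholds must be non-negative")
  structure(list(
    min_coverage_recall = min_coverage_recall,
    min_precision = min_precision,
    max_hole_area_fraction = max_hole_area_fraction,
    max_spurious_components = as.integer(max_spurious_components),
    max_mean_boundary_distance = max_mean_boundary_distance
  ), class = "validation_thresholds")
}

#' Criterion i: does the mask cover the entire wound?
#'
#' True iff recall of `pred` against `truth` is at least
#' `th$min_coverage_recall`. Coverage is one-sided: a dilated mask still
#' covers the wound.
#'
#' @param pred,truth binary masks of identical dimensions; `truth` non-empty.
#' @param th a [validation_thresholds()].
#' @return Logical scalar.
#' @export
check_coverage <- function(pred, truth, th = validation_thresholds()) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_shape(pred, truth)
  if (sum(truth) == 0) abort_wa("truth mask is empty: nothing to cover")
  rep <- metric_report(confusion_counts(pred, truth))
  rep$recall >= th$min_coverage_recall
}

# enclosed-background (hole) area via fill-hull complement
hole_area <- function(mask) {
  filled <- as.matrix(EBImage::fillHull(mask))
  sum(filled == 1 & mask == 0)
}

n_components <- function(mask) max(EBImage::bwlabel(mask))

#' Criterion ii: does the mask cover only the wound?
#'
#' True iff precision of `pred` against `truth` is at least
#' `th$min_precision`, the enclosed-background (hole) area does not exceed
#' `th$max_hole_area_fraction` of the mask area, and the number of foreground
#' components beyond the largest does not exceed
#' `th$max_spurious_components`.
#'
#' @inheritParams check_coverage
#' @return Logical scalar.
#' @export
check_only_wound <- function(pred, truth, th = validation_thresholds()) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_shape(pred, truth)
  if (sum(pred) == 0) return(FALSE)
  rep <- metric_report(confusion_counts(pred, truth))
  if (rep$precision < th$min_precision) return(FALSE)
  if (hole_area(pred) > th$max_hole_area_fraction * sum(pred)) return(FALSE)
  n_components(pred) - 1 <= th$max_spurious_components
}

# 1-px contour: foreground pixels with a 4-neighbour background pixel
boundary_pixels <- function(mask) {
  er <- as.matrix(EBImage::erode(mask, EBImage::makeBrush(3, "diamond")))
  mask == 1 & er == 0
}

#' Symmetric mean boundary distance between two masks
#'
#' Mean Euclidean distance from each contour pixel of one mask to the nearest
#' contour pixel of the other, pooled over both directions. Contours are the
#' 4-connected boundary pixels of each mask.
#'
#' @param pred,truth non-empty binary masks of identical dimensions.
#' @return Non-negative scalar, in pixels.
#' @export
mean_boundary_distance <- function(pred, truth) {
  bp <- boundary_pixels(pred)
  bt <- boundary_pixels(truth)
  if (!any(bp) || !any(bt)) abort_wa("cannot measure boundary of an empty mask")
  # distmap(x): distance of each foreground pixel of x to the nearest zero;
  # the complement of a contour therefore maps every pixel to its distance to
  # that contour
  d_to_t <- as.matrix(EBImage::distmap(matrix(as.integer(!bt), nrow(bt))))
  d_to_p <- as.matrix(EBImage::distmap(matrix(as.integer(!bp), nrow(bp))))
  mean(c(d_to_t[bp], d_to_p[bt]))
}

#' Criterion iii: does the mask follow the correct boundaries?
#'
#' True iff the symmetric mean boundary distance between the contours of
#' `pred` and `truth` is at most `th$max_mean_boundary_distance` times the
#' image diagonal. An empty prediction fails (returns `FALSE`, not an error).
#'
#' @inheritParams check_coverage
#' @return Logical scalar.
#' @export
check_boundary <- function(pred, truth, th = validation_thresholds()) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_shape(pred, truth)
  if (sum(truth) == 0) abort_wa("truth mask is empty")
  if (sum(pred) == 0) return(FALSE)
  diag_len <- sqrt(nrow(pred)^2 + ncol(pred)^2)
  mean_boundary_distance(pred, truth) <= th$max_mean_boundary_distance * diag_len
}

#' Simulated accept/discard validation of a predicted mask
#'
#' Evaluates the three acceptance criteria against a reference mask and
#' accepts iff all three hold. The oracle consumes only masks (never image
#' pixels), making it a pure, reproducible stand-in for the clinician
#' decision.
#'
#' @inheritParams check_coverage
#' @return A list of class `validation_result` with logical fields
#'   `covers_wound`, `only_wound`, `boundary_ok`, `accepted`.
#' @export
oracle_validate <- function(pred, truth, th = validation_thresholds()) {
  covers <- check_coverage(pred, truth, th)
  only <- check_only_wound(pred, truth, th)
  boundary <- if (sum(pred) == 0) FALSE else check_boundary(pred, truth, th)
  structure(list(
    covers_wound = covers,
    only_wound = only,
    boundary_ok = boundary,
    accepted = covers && only && boundary
  ), class = "validation_result")
}
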