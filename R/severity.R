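# Hough-circle diameter measurement and three-tier severity grading.
# Clinical convention: low risk D < 30 mm, moderate 30 <= D <= 55 mm
# (both thresholds inclusive in moderate), high D > 55 mm; a patient's
# severity comes from the maximum diameter over slices.

#' Edge map of a segmentation
#'
#' Binarizes a probability map if needed, then marks every foreground pixel
#' with at least one background 4-neighbour (image borders count as
#' background is *not* assumed: border foreground pixels are edges only if a
#' within-image neighbour is background or they touch the border).
#'
#' @param mask_or_map a [binary_mask()] or [probability_map()].
#' @param threshold binarization threshold for probability maps.
#' @return a [binary_mask()] of edge pixels (empty input gives an empty map).
#' @export
edge_map <- function(mask_or_map, threshold = 0.5) {
  x <- unclass(mask_or_map)
  if (any(x > 0 & x < 1)) x <- (x >= threshold) * 1
  h <- nrow(x)
  w <- ncol(x)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- x
  core <- pad[2:(h + 1), 2:(w + 1)]
  nb_min <- pmin(
    pad[1:h, 2:(w + 1)], pad[3:(h + 2), 2:(w + 1)],
    pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)]
  )
  rewrap((core == 1 & nb_min == 0) * 1, mask_or_map, "binary_mask")
}

#' Hough circle transform with a full 3-D accumulator
#'
#' Every edge pixel votes for all centers at every candidate integer radius
#' (rounded Euclidean distance). Peaks are accumulator cells that reach the
#' vote threshold and are maximal over their 3x3x3 neighbourhood, returned
#' highest-vote first with a deterministic tie-break (smaller radius, then
#' row-major center order).
#'
#' The default vote threshold is `min_votes_frac * 2 * pi * r`: on a
#' rasterized circle the boundary-pixel distances to the true center spread
#' over about one pixel, so the top cell typically collects roughly half the
#' circumference — hence the default fraction 0.35 rather than a stricter
#' one, which would reject perfect circles.
#'
#' @param edges edge [binary_mask()] (from [edge_map()]).
#' @param radius_range `c(rmin, rmax)` in pixels; defaults to
#'   `c(3, floor(min(dim) / 3))`.
#' @param min_votes absolute vote threshold (vector over radii or scalar);
#'   overrides `min_votes_frac`.
#' @param min_votes_frac fraction of the ideal circumference `2 pi r`
#'   required.
#' @return tibble of class `"hough_circles"`: `center_row`, `center_col`,
#'   `radius`, `votes`, sorted by votes (empty for an empty edge map).
#' @export
hough_circles <- function(edges, radius_range = NULL, min_votes = NULL,
                          min_votes_frac = 0.35) {
  x <- unclass(edges)
  radius_range <- radius_range %||% c(3, floor(min(dim(x)) / 3))
  rmin <- as.integer(radius_range[1])
  rmax <- as.integer(radius_range[2])
  if (rmin < 1) abort("hough_circles: rmin must be >= 1")
  if (rmax >= min(dim(x)) / 2) abort("hough_circles: rmax must be < image size / 2")
  radii <- rmin:rmax
  thr <- if (is.null(min_votes)) min_votes_frac * 2 * pi * radii else rep_len(min_votes, length(radii))
  out <- if (sum(x == 1) == 0) {
    tibble::tibble(
      center_row = integer(), center_col = integer(),
      radius = integer(), votes = integer()
    )
  } else {
    tibble::as_tibble(cpp_hough(matrix(as.integer(x == 1), nrow(x)), rmin, rmax, thr))
  }
  class(out) <- c("hough_circles", class(out))
  out
}

#' Sub-pixel radius refinement of a detected circle
#'
#' The integer Hough radius under-reads a rasterized disk: boundary pixel
#' *centers* sit up to one pixel inside the true outline. Refinement takes
#' the edge pixels within `band` pixels of the detected radius and averages
#' their distance to the detected center, then adds 0.5 px for the pixel
#' footprint (the physical region boundary lies half a pixel beyond the
#' boundary-pixel centers). This keeps diameter errors well below one pixel
#' spacing on clean masks.
#'
#' @param edges the edge map the circle was detected in.
#' @param circle one-row circle (from [hough_circles()]).
#' @param band radial window (px) of edge pixels used for the fit.
#' @return the circle row with `radius` replaced by the refined (fractional)
#'   radius.
#' @export
refine_circle <- function(edges, circle, band = 1.5) {
  co <- mask_coords(edges)
  d <- sqrt((co[, 1] - circle$center_row)^2 + (co[, 2] - circle$center_col)^2)
  keep <- abs(d - circle$radius) <= band
  if (!any(keep)) return(circle)
  circle$radius <- mean(d[keep]) + 0.5
  circle
}

#' Convert a detected circle radius to a diameter in mm
#'
#' @param circle a one-row circle tibble (or list with `radius` in px).
#' @param pixel_spacing_mm positive pixel spacing.
#' @return diameter in mm (`2 * radius * spacing`).
#' @export
measure_diameter_mm <- function(circle, pixel_spacing_mm) {
  if (pixel_spacing_mm <= 0) abort("measure_diameter_mm: spacing must be > 0")
  2 * circle$radius * pixel_spacing_mm
}

#' Detect the vessel circle in one segmented slice
#'
#' Convenience wrapper: edge map, Hough transform, top-vote circle, sub-pixel
#' refinement, diameter in mm.
#'
#' @param mask a [binary_mask()] or [probability_map()].
#' @param threshold binarization threshold.
#' @param ... passed to [hough_circles()].
#' @return one-row tibble `center_row, center_col, radius, votes, diameter_mm`,
#'   or a zero-row tibble when nothing is detected.
#' @export
detect_vessel_circle <- function(mask, threshold = 0.5, ...) {
  ed <- edge_map(mask, threshold)
  circ <- hough_circles(ed, ...)
  if (nrow(circ) == 0) {
    return(tibble::tibble(
      center_row = integer(), center_col = integer(), radius = numeric(),
      votes = integer(), diameter_mm = numeric()
    ))
  }
  top <- refine_circle(ed, circ[1, ])
  top$diameter_mm <- measure_diameter_mm(top, spacing_of(mask))
  top
}

#' Three-tier severity from a diameter
#'
#' @param diameter_mm positive diameter(s) in mm.
#' @return factor with levels `low` (< 30 mm), `moderate` (30-55 mm,
#'   inclusive) and `high` (> 55 mm).
#' @export
classify_severity <- function(diameter_mm) {
  if (any(diameter_mm <= 0)) abort("classify_severity: diameter must be > 0")
  factor(
    ifelse(diameter_mm < 30, "low",
      ifelse(diameter_mm <= 55, "moderate", "high")
    ),
    levels = severity_levels
  )
}

#' Patient-level severity from per-slice diameters
#'
#' The patient diameter is the maximum over slices (maximum aneurysm
#' diameter is the clinical standard); NA diameters (slices where no circle
#' was detected) are dropped, and a patient with no valid diameter at all is
#' flagged unclassifiable.
#'
#' @param slice_diameters numeric vector of per-slice diameters in mm (may
#'   contain NA).
#' @return list with `diameter_mm` and `class` (both NA if unclassifiable).
#' @export
patient_severity <- function(slice_diameters) {
  d <- slice_diameters[is.finite(slice_diameters)]
  if (length(d) == 0) {
    return(list(diameter_mm = NA_real_, class = factor(NA, levels = severity_levels)))
  }
  dm <- max(d)
  list(diameter_mm = dm, class = classify_severity(dm))
}

#' 3x3 severity confusion matrix
#'
#' Rows are predicted classes, columns are true classes (the orientation
#' under which per-row precision = diagonal / row sum and per-column
#' sensitivity = diagonal / column sum reproduce the reference analytics).
#'
#' @param pred,truth equal-length vectors coercible to severity factors.
#' @return 3x3 integer matrix of class `"confusion_matrix3"`.
#' @export
severity_confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("severity_confusion: length mismatch")
  pred <- factor(pred, levels = severity_levels)
  truth <- factor(truth, levels = severity_levels)
  m <- table(predicted = pred, true = truth)
  m <- matrix(as.integer(m), 3, 3,
    dimnames = list(predicted = severity_levels, true = severity_levels)
  )
  structure(m, class = c("confusion_matrix3", "matrix", "array"))
}

#' @method tidy confusion_matrix3
#' @export
tidy.confusion_matrix3 <- function(x, ...) {
  tibble::tibble(
    predicted = rep(severity_levels, 3),
    true = rep(severity_levels, each = 3),
    n = as.integer(unclass(x))
  )
}

#' Per-class and macro sensitivity / precision / accuracy
#'
#' Per-class sensitivity = diagonal / column (true-class) sum; per-class
#' precision = diagonal / row (predicted-class) sum; per-class "accuracy"
#' equals per-class sensitivity — the convention of the reference analytics,
#' where the printed accuracy column duplicates sensitivity. Macro values are
#' unweighted means over the three classes; classes with a zero column (for
#' sensitivity) or zero row (for precision) are excluded from the macro mean
#' with a warning.
#'
#' @param cm a [severity_confusion()] matrix.
#' @return object of class `"class_metrics"`: tibble with rows low, moderate,
#'   high, macro and columns `sensitivity`, `precision`, `accuracy` (percent).
#' @export
class_metrics <- function(cm) {
  m <- unclass(cm)
  if (sum(m) == 0) abort("class_metrics: empty confusion matrix")
  diagm <- unname(diag(m))
  colsum <- unname(colSums(m))
  rowsum <- unname(rowSums(m))
  sens <- 100 * diagm / colsum
  prec <- 100 * diagm / rowsum
  if (any(colsum == 0)) warn("class_metrics: class(es) with no true cases excluded from macro sensitivity")
  if (any(rowsum == 0)) warn("class_metrics: class(es) never predicted excluded from macro precision")
  macro_sens <- mean(sens[colsum > 0])
  macro_prec <- mean(prec[rowsum > 0])
  out <- tibble::tibble(
    class = c(severity_levels, "macro"),
    sensitivity = c(sens, macro_sens),
    precision = c(prec, macro_prec),
    accuracy = c(sens, macro_sens)
  )
  class(out) <- c("class_metrics", class(out))
  out
}

#' Classify every patient of a cohort from segmentation masks
#'
#' Runs circle detection on each slice mask, takes the per-patient maximum
#' diameter and grades severity; pairs the result with the cohort's true
#' classes.
#'
#' @param cohort manifest from [generate_cohort()] (or any tibble with
#'   `patient_id` and `true_class`).
#' @param masks named list: for each patient id, a list of per-slice masks
#'   (binary or probability).
#' @param threshold binarization threshold for probability maps.
#' @param ... passed to [hough_circles()].
#' @return tibble: `patient_id`, `diameter_mm`, `pred_class`, `true_class`.
#' @export
classify_cohort <- function(cohort, masks, threshold = 0.5, ...) {
  purrr::map_dfr(cohort$patient_id, function(pid) {
    ms <- masks[[pid]]
    diam <- vapply(ms, function(m) {
      det <- detect_vessel_circle(m, threshold, ...)
      if (nrow(det) == 0) NA_real_ else det$diameter_mm
    }, 0)
    ps <- patient_severity(diam)
    tibble::tibble(
      patient_id = pid, diameter_mm = ps$diameter_mm, pred_class = ps$class,
      true_class = cohort$true_class[cohort$patient_id == pid]
    )
  })
}
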