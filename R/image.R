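#' 2-D grayscale image slices and masks
#'
#' The pipeline operates on plain numeric matrices carrying three attributes:
#' `pixel_spacing_mm` (physical size of one pixel), `patient_id` and
#' `slice_index`. `image2d()` holds intensities in \[0, 1\]; `binary_mask()`
#' holds hard \{0, 1\} labels (foreground = vessel); `probability_map()` holds
#' per-pixel segmentation confidence in \[0, 1\].
#'
#' @param values numeric matrix; all values finite.
#' @param pixel_spacing_mm positive scalar, millimetres per pixel.
#' @param patient_id opaque patient identifier.
#' @param slice_index integer slice position (>= 0).
#' @return a matrix of class `"image2d"`, `"binary_mask"` or
#'   `"probability_map"` with spatial metadata attached.
#' @export
image2d <- function(values, pixel_spacing_mm = 1, patient_id = NA_character_,
                    slice_index = 0L) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) abort("image2d: all values must be finite")
  if (min(values) < 0 || max(values) > 1)
    abort("image2d: intensities must lie in [0, 1]")
  if (pixel_spacing_mm <= 0) abort("image2d: pixel_spacing_mm must be > 0")
  structure(values,
    pixel_spacing_mm = pixel_spacing_mm,
    patient_id = patient_id, slice_index = as.integer(slice_index),
    class = c("image2d", "matrix", "array")
  )
}

#' @rdname image2d
#' @export
binary_mask <- function(values, pixel_spacing_mm = 1, patient_id = NA_character_,
                        slice_index = 0L) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) abort("binary_mask: values must be 0 or 1")
  structure(values * 1,
    pixel_spacing_mm = pixel_spacing_mm,
    patient_id = patient_id, slice_index = as.integer(slice_index),
    class = c("binary_mask", "matrix", "array")
  )
}

#' @rdname image2d
#' @export
probability_map <- function(values, pixel_spacing_mm = 1,
                            patient_id = NA_character_, slice_index = 0L) {
  values <- as.matrix(values)
  if (!all(is.finite(values)) || min(values) < 0 || max(values) > 1)
    abort("probability_map: values must lie in [0, 1]")
  structure(values,
    pixel_spacing_mm = pixel_spacing_mm,
    patient_id = patient_id, slice_index = as.integer(slice_index),
    class = c("probability_map", "matrix", "array")
  )
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf(
    "<image2d %d x %d, %.3g mm/px, patient %s, slice %d, range [%.3f, %.3f]>\n",
    nrow(x), ncol(x), attr(x, "pixel_spacing_mm"),
    as.character(attr(x, "patient_id")), attr(x, "slice_index"),
    min(x), max(x)
  ))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask %d x %d, %.3g mm/px, %d foreground px>\n",
    nrow(x), ncol(x), attr(x, "pixel_spacing_mm"), sum(x == 1)
  ))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf(
    "<probability_map %d x %d, range [%.3f, %.3f]>\n",
    nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}

spacing_of <- function(x) {
  s <- attr(x, "pixel_spacing_mm")
  if (is.null(s)) 1 else s
}

# rebuild an image-like object from new values, keeping metadata
rewrap <- function(values, template, class = "image2d") {
  structure(as.matrix(values),
    pixel_spacing_mm = spacing_of(template),
    patient_id = attr(template, "patient_id"),
    slice_index = attr(template, "slice_index"),
    class = c(class, "matrix", "array")
  )
}

# Keys bicubic kernel, a = -0.5
bicubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
    ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0)
  )
}

# dense (n_out x n_in) row-resampling operator, edge-clamped, rows sum to 1
bicubic_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) * scale - 0.5 # 0-based source position
    base <- floor(src)
    for (k in -1:2) {
      idx <- base + k
      w <- bicubic_kernel(src - idx)
      idx <- min(max(idx, 0), n_in - 1)
      W[o, idx + 1] <- W[o, idx + 1] + w
    }
  }
  sweep(W, 1, rowSums(W), "/")
}

#' Bicubic resampling of an image slice
#'
#' Separable bicubic interpolation (Keys kernel, a = -0.5) with edge
#' clamping, matching the usual preprocessing step that rescales acquired
#' 512 x 512 slices to the 256 x 256 network input. The pixel spacing is
#' rescaled by the size ratio so physical diameters are preserved, and
#' intensities are clipped back to \[0, 1\].
#'
#' @param image an [image2d()] (or plain matrix in \[0, 1\]).
#' @param target_size integer target side length (scalar, or length-2
#'   `c(rows, cols)`).
#' @return an [image2d()] of the requested size.
#' @export
resize_bicubic <- function(image, target_size) {
  target_size <- as.integer(target_size)
  if (length(target_size) == 1) target_size <- c(target_size, target_size)
  if (any(target_size <= 0)) abort("resize_bicubic: target size must be positive")
  x <- unclass(image)
  Wr <- bicubic_weights(nrow(x), target_size[1])
  Wc <- bicubic_weights(ncol(x), target_size[2])
  out <- Wr %*% x %*% t(Wc)
  out <- pmin(pmax(out, 0), 1)
  ratio <- nrow(x) / target_size[1]
  image2d(out,
    pixel_spacing_mm = spacing_of(image) * ratio,
    patient_id = attr(image, "patient_id"),
    slice_index = if (is.null(attr(image, "slice_index"))) 0L else attr(image, "slice_index")
  )
}

#' Stack per-slice masks into a 3-D binary volume
#'
#' Axial masks ordered by slice index are stacked along z so that voxel
#' `(z, y, x)` equals `mask_z(y, x)`; this is the volume underlying 3-D
#' surface renderings of a segmented aneurysm.
#'
#' @param masks list of same-shaped [binary_mask()] objects, in z order.
#' @return 3-D 0/1 array with dim `(n_slices, H, W)`.
#' @export
stack_masks_to_volume <- function(masks) {
  if (length(masks) == 0) abort("stack_masks_to_volume: empty mask list")
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("stack_masks_to_volume: masks differ in shape")
  vol <- array(0, dim = c(length(masks), dims[1, 1], dims[2, 1]))
  for (z in seq_along(masks)) vol[z, , ] <- unclass(masks[[z]])
  vol
}
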