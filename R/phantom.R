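# Synthetic vessel-phantom cohorts. The study's clinical CT slices are not
# deposited, so phantoms stand in: a bright quasi-circular aneurysm
# cross-section of known diameter on a textured soft-tissue background with
# a few dimmer organ blobs, 256 x 256 by default, 80-140 slices per patient,
# severity mix defaulting to the 4/12/19 low/moderate/high cohort.

# diameter bands per severity class; each stays >= 2 mm away from the
# 30 mm / 55 mm thresholds so clean-phantom classification has no boundary cases
severity_bands <- list(
  low = c(18, 28), moderate = c(32, 53), high = c(57, 70)
)

severity_levels <- c("low", "moderate", "high")

#' Specify a vessel phantom
#'
#' @param image_size pixels per side (square slices).
#' @param pixel_spacing_mm millimetres per pixel (> 0). The clinical pixel
#'   spacing of the reference protocol is unknown; 1.5 mm/px is a stand-in
#'   giving a 384 mm field of view at 256 px.
#' @param vessel_diameter_mm true aneurysm (major-axis) diameter, 15-70 mm.
#' @param ellipticity minor/major axis ratio in \[0.8, 1\].
#' @param background_level mean soft-tissue intensity in (0, 1).
#' @param texture_sd standard deviation of the Gaussian background texture.
#' @param vessel_level vessel plateau intensity; must exceed
#'   `background_level + 0.2`.
#' @param n_blobs range (length 2) or fixed count of dimmer "organ" blobs
#'   added to the background; their intensity is capped 0.1 below the vessel
#'   plateau. Use 0 for a plain background.
#' @param jitter per-slice fractional diameter jitter (default 2%), clipped so
#'   a slice never leaves its severity band.
#' @param diameter_bounds optional c(lo, hi) clamp for the jittered diameter;
#'   defaults to the severity band containing `vessel_diameter_mm` (or, off a
#'   band, the class interval) so jitter cannot change the true class.
#' @param n_slices slices for this patient.
#' @param seed integer RNG seed; slices are deterministic given
#'   `(seed, slice_index)`.
#' @param patient_id identifier stamped on generated slices.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_size = 256, pixel_spacing_mm = 1.5,
                         vessel_diameter_mm = 40, ellipticity = 1,
                         background_level = 0.3, texture_sd = 0.03,
                         vessel_level = 0.5, n_blobs = c(1, 3),
                         jitter = 0.02, diameter_bounds = NULL,
                         n_slices = 100, seed = 1, patient_id = "P000") {
  if (pixel_spacing_mm <= 0) abort("phantom_spec: pixel_spacing_mm must be > 0")
  if (vessel_diameter_mm < 15 || vessel_diameter_mm > 70)
    abort("phantom_spec: vessel_diameter_mm must lie in [15, 70]")
  if (ellipticity < 0.8 || ellipticity > 1)
    abort("phantom_spec: ellipticity must lie in [0.8, 1]")
  if (background_level <= 0 || background_level >= 1)
    abort("phantom_spec: background_level must lie in (0, 1)")
  if (texture_sd < 0) abort("phantom_spec: texture_sd must be >= 0")
  if (vessel_level < background_level + 0.2 || vessel_level > 1)
    abort("phantom_spec: vessel_level must lie in [background_level + 0.2, 1]")
  if (vessel_diameter_mm / pixel_spacing_mm >= image_size)
    abort(sprintf(
      "phantom_spec: vessel (%.1f mm = %.1f px) does not fit in a %d px field of view",
      vessel_diameter_mm, vessel_diameter_mm / pixel_spacing_mm, image_size
    ))
  if (length(n_blobs) == 1) n_blobs <- c(n_blobs, n_blobs)
  structure(
    list(
      image_size = as.integer(image_size), pixel_spacing_mm = pixel_spacing_mm,
      vessel_diameter_mm = vessel_diameter_mm, ellipticity = ellipticity,
      background_level = background_level, texture_sd = texture_sd,
      vessel_level = vessel_level, n_blobs = as.integer(n_blobs),
      jitter = jitter, diameter_bounds = diameter_bounds,
      n_slices = as.integer(n_slices), seed = as.integer(seed),
      patient_id = patient_id
    ),
    class = "phantom_spec"
  )
}

# interval the jittered diameter may occupy without changing class
class_interval <- function(d) {
  for (cls in severity_levels) {
    b <- severity_bands[[cls]]
    if (d >= b[1] && d <= b[2]) return(b)
  }
  if (d < 30) c(15, 30 - 1e-6) else if (d <= 55) c(30, 55) else c(55 + 1e-6, 70)
}

# anti-aliased ellipse coverage and hard membership on the pixel grid
ellipse_fields <- function(n, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(n), each = n), n, n) # column index (x)
  ys <- matrix(rep(seq_len(n), times = n), n, n) # row index (y)
  dx <- xs - cx
  dy <- ys - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  f <- sqrt((xr / a)^2 + (yr / b)^2)
  inside <- f <= 1
  # approximate signed distance (px) to the ellipse boundary, for AA blending
  e <- (f - 1) * min(a, b)
  coverage <- pmin(pmax(0.5 - e, 0), 1)
  list(inside = inside, coverage = coverage)
}

#' Generate one phantom slice
#'
#' Renders the aneurysm cross-section as a filled ellipse whose major axis is
#' `round(vessel_diameter_mm / pixel_spacing_mm)` pixels. The binary mask is
#' hard (no anti-aliasing) so overlap metrics are exact; the image plateau
#' edge is anti-aliased over one pixel. The per-slice diameter is jittered by
#' up to `spec$jitter` (clipped to the severity band) to mimic anatomical
#' variation along z.
#'
#' @param spec a [phantom_spec()].
#' @param slice_index integer in `0:(n_slices - 1)`.
#' @return list with `image` ([image2d()]), `mask` ([binary_mask()]) and
#'   `true_diameter_mm` (the jittered major-axis diameter of this slice).
#' @export
generate_slice <- function(spec, slice_index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (slice_index < 0 || slice_index >= spec$n_slices)
    abort("generate_slice: slice_index out of range")
  n <- spec$image_size
  with_seed(derive_seed(spec$seed, slice_index + 1L), {
    bounds <- spec$diameter_bounds %||% class_interval(spec$vessel_diameter_mm)
    d <- spec$vessel_diameter_mm * runif(1, 1 - spec$jitter, 1 + spec$jitter)
    d <- min(max(d, bounds[1]), bounds[2])
    d_px <- round(d / spec$pixel_spacing_mm)
    a <- d_px / 2
    b <- spec$ellipticity * a
    m <- max(0, min(0.05 * n, (n - d_px) / 2 - 2))
    cx <- n / 2 + 0.5 + round(runif(1, -m, m))
    cy <- n / 2 + 0.5 + round(runif(1, -m, m))
    theta <- runif(1, 0, pi)
    ves <- ellipse_fields(n, cx, cy, a, b, theta)
    tissue <- matrix(spec$background_level, n, n)
    nb <- if (spec$n_blobs[2] > 0) sample(spec$n_blobs[1]:spec$n_blobs[2], 1) else 0L
    for (k in seq_len(nb)) {
      bl_level <- runif(1, spec$background_level + 0.05, spec$vessel_level - 0.1)
      bl_a <- runif(1, 0.03, 0.12) * n
      bl <- ellipse_fields(
        n, runif(1, 0.15 * n, 0.85 * n), runif(1, 0.15 * n, 0.85 * n),
        bl_a, runif(1, 0.6, 1) * bl_a, runif(1, 0, pi)
      )
      tissue <- tissue + bl$coverage * (bl_level - spec$background_level)
    }
    tissue <- pmin(tissue, spec$vessel_level - 0.1)
    noise <- if (spec$texture_sd > 0) {
      matrix(rnorm(n * n, 0, spec$texture_sd), n, n)
    } else 0
    img <- tissue + ves$coverage * (spec$vessel_level - tissue) + noise
    img <- pmin(pmax(img, 0), 1)
    list(
      image = image2d(img, spec$pixel_spacing_mm, spec$patient_id, slice_index),
      mask = binary_mask(
        ves$inside * 1, spec$pixel_spacing_mm, spec$patient_id, slice_index
      ),
      true_diameter_mm = d_px * spec$pixel_spacing_mm
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic patient cohort manifest
#'
#' Each patient receives one true diameter drawn uniformly within its severity
#' band (low \[18, 28\], moderate \[32, 53\], high \[57, 70\] mm; every band
#' keeps a 2 mm guard away from the 30/55 mm thresholds) and a slice count
#' drawn from `slices_per_patient`. Slices are generated lazily by
#' [generate_patient_slices()] so large cohorts never need to sit in memory.
#'
#' @param n_patients number of patients; must equal `sum(severity_mix)`.
#' @param severity_mix integer c(low, moderate, high) counts; the default
#'   4/12/19 matches the clinical cohort's severity distribution.
#' @param slices_per_patient inclusive range for per-patient slice counts.
#' @param master_seed single integer; the whole cohort is reproducible from it.
#' @param image_size,pixel_spacing_mm,ellipticity,background_level,texture_sd,vessel_level,n_blobs
#'   forwarded to [phantom_spec()] for every patient.
#' @return tibble with one row per patient: `patient_id`, `true_class`,
#'   `true_diameter_mm`, `n_slices`, `patient_seed`, plus the shared phantom
#'   parameters.
#' @export
generate_cohort <- function(n_patients = 35, severity_mix = c(4, 12, 19),
                            slices_per_patient = c(80, 140), master_seed = 1,
                            image_size = 256, pixel_spacing_mm = 1.5,
                            ellipticity = 1, background_level = 0.3,
                            texture_sd = 0.03, vessel_level = 0.5,
                            n_blobs = c(1, 3)) {
  if (any(severity_mix < 0)) abort("generate_cohort: severity_mix counts must be >= 0")
  if (sum(severity_mix) != n_patients)
    abort("generate_cohort: n_patients must equal sum(severity_mix)")
  classes <- rep(severity_levels, times = severity_mix)
  rows <- purrr::map_dfr(seq_len(n_patients), function(i) {
    s <- derive_seed(master_seed, i)
    with_seed(s, {
      band <- severity_bands[[classes[i]]]
      tibble::tibble(
        patient_id = sprintf("P%03d", i),
        true_class = factor(classes[i], levels = severity_levels),
        true_diameter_mm = runif(1, band[1], band[2]),
        n_slices = {
          rng <- slices_per_patient[1]:slices_per_patient[2]
          if (length(rng) == 1) rng else sample(rng, 1)
        },
        patient_seed = s
      )
    })
  })
  rows$image_size <- as.integer(image_size)
  rows$pixel_spacing_mm <- pixel_spacing_mm
  rows$ellipticity <- ellipticity
  rows$background_level <- background_level
  rows$texture_sd <- texture_sd
  rows$vessel_level <- vessel_level
  rows$n_blobs_min <- as.integer(n_blobs[1])
  rows$n_blobs_max <- as.integer(n_blobs[length(n_blobs)])
  rows
}

#' Materialize all slices of one cohort patient
#'
#' @param cohort manifest from [generate_cohort()].
#' @param patient row index or `patient_id`.
#' @return list of per-slice lists as returned by [generate_slice()].
#' @export
generate_patient_slices <- function(cohort, patient) {
  i <- if (is.character(patient)) match(patient, cohort$patient_id) else patient
  if (is.na(i) || i < 1 || i > nrow(cohort))
    abort("generate_patient_slices: unknown patient")
  row <- cohort[i, ]
  spec <- phantom_spec(
    image_size = row$image_size, pixel_spacing_mm = row$pixel_spacing_mm,
    vessel_diameter_mm = row$true_diameter_mm, ellipticity = row$ellipticity,
    background_level = row$background_level, texture_sd = row$texture_sd,
    vessel_level = row$vessel_level,
    n_blobs = c(row$n_blobs_min, row$n_blobs_max),
    diameter_bounds = severity_bands[[as.character(row$true_class)]],
    n_slices = row$n_slices, seed = row$patient_seed,
    patient_id = row$patient_id
  )
  lapply(seq_len(row$n_slices) - 1L, function(z) generate_slice(spec, z))
}
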