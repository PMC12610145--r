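# Fixtures built in code: rasterized disks, tiny cohorts, naive reference
# filters used as independent oracles.

# hard disk/ellipse mask on an n x n grid, center defaults to the half-integer
# grid center so even diameters rasterize symmetrically
make_disk_mask <- function(n, r, cx = n / 2 + 0.5, cy = cx, spacing = 1) {
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), times = n), n)
  binary_mask(((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1, pixel_spacing_mm = spacing)
}

random_mask <- function(n, p = 0.3) {
  binary_mask(matrix(rbinom(n * n, 1, p), n, n))
}

# naive double-loop reference filters with symmetric (reflect) padding;
# deliberately independent of the package's sliding-window engine
reflect_index <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

naive_window <- function(x, r0, c0, wh, ww) {
  rh <- wh %/% 2
  rw <- ww %/% 2
  vals <- numeric(0)
  for (dj in -rw:rw) {
    for (di in -rh:rh) {
      vals <- c(vals, x[
        reflect_index(r0 + di, nrow(x)),
        reflect_index(c0 + dj, ncol(x))
      ])
    }
  }
  vals
}

naive_filter <- function(x, kind, window = c(3, 3), kernel = NULL, sn2 = 0) {
  out <- x
  for (c0 in seq_len(ncol(x))) {
    for (r0 in seq_len(nrow(x))) {
      v <- naive_window(x, r0, c0, window[1], window[2])
      out[r0, c0] <- switch(kind,
        average = sum(v * as.vector(kernel)),
        median = median(v),
        wiener = {
          mu <- mean(v)
          s2 <- mean((v - mu)^2)
          g <- min(max((s2 - sn2) / max(s2, 1e-12), 0), 1)
          mu + g * (x[r0, c0] - mu)
        },
        mmwf = {
          mu <- mean(v)
          s2 <- mean((v - mu)^2)
          ml <- median(v)
          g <- min(max((s2 - sn2) / max(s2, 1e-12), 0), 1)
          ml + g * (x[r0, c0] - ml)
        }
      )
    }
  }
  pmin(pmax(out, 0), 1)
}

# small all-in-memory cohort: list(images, masks, cohort)
tiny_cohort <- function(n_patients = 6, mix = c(2, 2, 2), slices = 4,
                        image_size = 64, spacing = 1.75, seed = 7) {
  cohort <- generate_cohort(
    n_patients = n_patients, severity_mix = mix,
    slices_per_patient = c(slices, slices), master_seed = seed,
    image_size = image_size, pixel_spacing_mm = spacing
  )
  all <- lapply(seq_len(n_patients), function(i) generate_patient_slices(cohort, i))
  list(
    cohort = cohort,
    images = unlist(lapply(all, function(s) lapply(s, `[[`, "image")), recursive = FALSE),
    masks = unlist(lapply(all, function(s) lapply(s, `[[`, "mask")), recursive = FALSE),
    diameters = unlist(lapply(all, function(s) lapply(s, `[[`, "true_diameter_mm")))
  )
}
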