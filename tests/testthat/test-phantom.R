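test_that("rasterized vessel geometry matches its specification", {
  # 30 mm at 1.5 mm/px: major chord of the mask is exactly 20 px
  s <- phantom_spec(
    image_size = 128, vessel_diameter_mm = 30, pixel_spacing_mm = 1.5,
    ellipticity = 1, jitter = 0, texture_sd = 0, n_blobs = 0
  )
  sl <- generate_slice(s, 0)
  expect_equal(max(rowSums(sl$mask == 1)), 20)
  expect_equal(max(colSums(sl$mask == 1)), 20)
  expect_equal(sl$true_diameter_mm, 30)

  # 60 mm disk: foreground area within 2% of a brute-force point-in-circle count
  s2 <- phantom_spec(
    image_size = 128, vessel_diameter_mm = 60, pixel_spacing_mm = 1.5,
    ellipticity = 1, jitter = 0, texture_sd = 0, n_blobs = 0
  )
  sl2 <- generate_slice(s2, 0)
  # brute-force point-in-circle count (translation by whole pixels is exact)
  oracle <- sum(make_disk_mask(128, 20) == 1)
  expect_equal(sum(sl2$mask == 1), oracle)
  expect_lt(abs(sum(sl2$mask == 1) - pi * 20^2) / (pi * 20^2), 0.02)
})

test_that("zero-texture background is exactly flat away from the vessel", {
  s <- phantom_spec(
    image_size = 96, vessel_diameter_mm = 30, pixel_spacing_mm = 1.5,
    background_level = 0.3, texture_sd = 0, n_blobs = 0, jitter = 0
  )
  sl <- generate_slice(s, 0)
  # pixels farther than 1 px from the mask are untouched by the anti-aliased rim
  fg <- which(unclass(sl$mask) == 1, arr.ind = TRUE)
  bg <- which(unclass(sl$mask) == 0, arr.ind = TRUE)
  d <- aaaseg:::cpp_nearest_dist(bg, fg)
  expect_true(all(sl$image[bg[d > 1.5, ]] == 0.3))
  # and vessel interior sits at the plateau, >= background + 0.2
  expect_true(all(sl$image[fg[aaaseg:::cpp_nearest_dist(fg, bg) > 1.5, ]] >= 0.3 + 0.2))
})

test_that("an oversized vessel is rejected with a clear error", {
  expect_error(
    phantom_spec(image_size = 32, vessel_diameter_mm = 60, pixel_spacing_mm = 1),
    "fit"
  )
})

test_that("cohort generation respects the severity mix and is reproducible", {
  co <- generate_cohort(35, c(4, 12, 19),
    slices_per_patient = c(80, 140),
    master_seed = 42
  )
  expect_equal(nrow(co), 35)
  expect_equal(as.integer(table(co$true_class)), c(4, 12, 19))
  expect_true(all(co$n_slices >= 80 & co$n_slices <= 140))
  co2 <- generate_cohort(35, c(4, 12, 19),
    slices_per_patient = c(80, 140),
    master_seed = 42
  )
  expect_identical(co, co2)

  one <- generate_cohort(1, c(1, 0, 0), slices_per_patient = c(3, 3), master_seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_slices, 3)
  expect_equal(as.character(one$true_class), "low")

  expect_error(generate_cohort(2, c(3, -1, 0)), ">= 0")
  expect_error(generate_cohort(5, c(1, 1, 1)), "sum")
})

test_that("no generated diameter comes within 2 mm of a severity threshold", {
  co <- generate_cohort(60, c(20, 20, 20),
    slices_per_patient = c(2, 2),
    master_seed = 9, image_size = 64, pixel_spacing_mm = 1.75
  )
  expect_true(all(abs(co$true_diameter_mm - 30) >= 2))
  expect_true(all(abs(co$true_diameter_mm - 55) >= 2))
  bands <- list(low = c(18, 28), moderate = c(32, 53), high = c(57, 70))
  for (cls in names(bands)) {
    d <- co$true_diameter_mm[co$true_class == cls]
    expect_true(all(d >= bands[[cls]][1] & d <= bands[[cls]][2]))
  }
  # per-slice jitter stays inside the class band too
  sl <- unlist(lapply(1:10, function(i) {
    lapply(generate_patient_slices(co, i), `[[`, "true_diameter_mm")
  }))
  expect_true(all(sl >= 18 - 1e-9 & sl <= 28 + 1e-9))
})

test_that("mask inscribed-circle diameter tracks the slice's true diameter", {
  co <- generate_cohort(6, c(2, 2, 2),
    slices_per_patient = c(2, 2),
    master_seed = 5, image_size = 128, pixel_spacing_mm = 1.5
  )
  for (i in seq_len(6)) {
    for (sl in generate_patient_slices(co, i)) {
      fg <- which(unclass(sl$mask) == 1, arr.ind = TRUE)
      bg <- which(unclass(sl$mask) == 0, arr.ind = TRUE)
      # brute-force distance transform: deepest interior pixel + pixel footprint
      inscribed_px <- 2 * max(aaaseg:::cpp_nearest_dist(fg, bg)) + 1
      expect_lt(
        abs(inscribed_px * 1.5 - sl$true_diameter_mm),
        1.5 + 1e-9
      )
    }
  }
})

test_that("slice generation is deterministic and slices differ across indices", {
  s <- phantom_spec(image_size = 64, vessel_diameter_mm = 40, pixel_spacing_mm = 1.75, seed = 3)
  a <- generate_slice(s, 2)
  b <- generate_slice(s, 2)
  expect_identical(a, b)
  c_ <- generate_slice(s, 3)
  expect_false(identical(unclass(a$image), unclass(c_$image)))
  expect_error(generate_slice(s, s$n_slices), "out of range")
})
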