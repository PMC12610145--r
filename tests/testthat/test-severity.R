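test_that("edge maps mark the 4-connected boundary", {
  disk <- make_disk_mask(64, 10)
  ed <- edge_map(disk)
  # boundary length tracks the circumference; the 4-connected staircase
  # boundary of a rasterized circle is systematically a little shorter than
  # 2*pi*r (56 px vs 62.8 at r = 10), so the sanity band is 15%
  expect_lt(abs(sum(ed == 1) - 2 * pi * 10) / (2 * pi * 10), 0.15)
  # oracle: foreground pixels with a background 4-neighbour
  x <- unclass(disk)
  want <- matrix(0, 64, 64)
  for (i in 1:64) {
    for (j in 1:64) {
      if (x[i, j] == 1) {
        nb <- c(
          if (i > 1) x[i - 1, j] else 0, if (i < 64) x[i + 1, j] else 0,
          if (j > 1) x[i, j - 1] else 0, if (j < 64) x[i, j + 1] else 0
        )
        if (any(nb == 0)) want[i, j] <- 1
      }
    }
  }
  expect_equal(unclass(ed), want, ignore_attr = TRUE)

  expect_equal(sum(edge_map(binary_mask(matrix(0, 8, 8)))), 0)
  single <- binary_mask(matrix(c(rep(0, 12), 1, rep(0, 12)), 5, 5))
  expect_equal(unclass(edge_map(single)), unclass(single))
  # probability maps are binarized first
  pm <- probability_map(matrix(0.7, 5, 5))
  expect_equal(sum(edge_map(pm, 0.5) == 1), 16) # border ring of an all-fg map
})

test_that("Hough voting matches an exhaustive accumulator and recovers radii", {
  # small image: brute-force accumulator over every (center, radius) cell
  m <- make_disk_mask(48, 9, cx = 20.5, cy = 26.5)
  ed <- edge_map(m)
  got <- hough_circles(ed, radius_range = c(3, 15), min_votes = 1)
  ec <- which(unclass(ed) == 1, arr.ind = TRUE)
  best <- c(-1, 0, 0, 0)
  for (r in 3:15) {
    votes <- matrix(0, 48, 48)
    for (cy in 1:48) {
      for (cx in 1:48) {
        dd <- round(sqrt((ec[, 1] - cy)^2 + (ec[, 2] - cx)^2))
        votes[cy, cx] <- sum(dd == r)
      }
    }
    mx <- max(votes)
    if (mx > best[1]) {
      w <- which(votes == mx, arr.ind = TRUE)[1, ]
      best <- c(mx, w[1], w[2], r)
    }
  }
  expect_equal(got$votes[1], unname(best[1]))
  expect_equal(got$radius[1], unname(best[4]))
  expect_lte(abs(got$center_row[1] - 26.5), 1)
  expect_lte(abs(got$center_col[1] - 20.5), 1)

  # ideal circle at the image center: within 1 px in center and radius
  big <- make_disk_mask(256, 20)
  top <- hough_circles(edge_map(big))[1, ]
  expect_lte(abs(top$center_row - 128.5), 1)
  expect_lte(abs(top$center_col - 128.5), 1)
  expect_lte(abs(top$radius - 20), 1)

  expect_equal(nrow(hough_circles(binary_mask(matrix(0, 64, 64)))), 0)

  # two separated disks: both found, the larger circle gathers more votes
  two <- matrix(0, 128, 128)
  two[unclass(make_disk_mask(128, 10, cx = 30.5, cy = 30.5)) == 1] <- 1
  two[unclass(make_disk_mask(128, 25, cx = 85.5, cy = 85.5)) == 1] <- 1
  circ <- hough_circles(edge_map(binary_mask(two)))
  expect_gte(nrow(circ), 2)
  expect_lte(abs(circ$radius[1] - 25), 1)
  small_hit <- circ[abs(circ$center_row - 30.5) < 2 & abs(circ$center_col - 30.5) < 2, ]
  expect_gte(nrow(small_hit), 1)
  expect_lte(abs(small_hit$radius[1] - 10), 1)
  expect_gt(circ$votes[1], small_hit$votes[1])

  expect_error(hough_circles(edge_map(big), radius_range = c(0, 10)), "rmin")
  expect_error(hough_circles(edge_map(big), radius_range = c(3, 200)), "rmax")
})

test_that("refined diameters land within the stated tolerance", {
  expect_equal(measure_diameter_mm(list(radius = 20), 1.5), 60)
  expect_equal(measure_diameter_mm(list(radius = 10), 1), 20)
  expect_error(measure_diameter_mm(list(radius = 10), 0), "> 0")

  # clean phantom mask, true diameter 40 mm: measured within 2 pixel spacings
  s <- phantom_spec(
    image_size = 128, vessel_diameter_mm = 40, pixel_spacing_mm = 1.5,
    jitter = 0, texture_sd = 0, n_blobs = 0
  )
  det <- detect_vessel_circle(generate_slice(s, 0)$mask)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$diameter_mm - 40), 2 * 1.5)
})

test_that("severity thresholds are a monotone step with 30 and 55 in moderate", {
  expect_equal(as.character(classify_severity(25)), "low")
  expect_equal(as.character(classify_severity(29.999)), "low")
  expect_equal(as.character(classify_severity(30)), "moderate")
  expect_equal(as.character(classify_severity(55)), "moderate")
  expect_equal(as.character(classify_severity(55.001)), "high")
  expect_equal(as.character(classify_severity(56)), "high")
  expect_error(classify_severity(0), "> 0")
  # monotone step over a fine grid
  g <- classify_severity(seq(1, 70, by = 0.25))
  expect_true(all(diff(as.integer(g)) >= 0))
})

test_that("patient severity takes the maximum slice diameter", {
  p <- patient_severity(c(28, 31, 29))
  expect_equal(p$diameter_mm, 31)
  expect_equal(as.character(p$class), "moderate")
  expect_equal(as.character(patient_severity(60)$class), "high")
  un <- patient_severity(c(NA_real_, NA_real_))
  expect_true(is.na(un$diameter_mm) && is.na(un$class))
})

test_that("confusion matrix orientation is predicted-by-true", {
  truth <- rep(c("low", "moderate", "high"), times = c(4, 12, 19))
  cm <- severity_confusion(truth, truth)
  expect_equal(diag(unclass(cm)), setNames(c(4L, 12L, 19L), c("low", "moderate", "high")))
  expect_equal(sum(unclass(cm)) - sum(diag(unclass(cm))), 0)

  empty <- severity_confusion(character(0), character(0))
  expect_true(all(unclass(empty) == 0))
  expect_error(severity_confusion(c("low"), c("low", "high")), "length")

  pred <- c("low", "moderate", "high")
  cm2 <- severity_confusion(pred, c("moderate", "moderate", "moderate"))
  expect_equal(unclass(cm2)["low", "moderate"], 1L)
  expect_equal(sum(tidy(cm2)$n), 3L)
})

test_that("per-class analytics use the sensitivity-as-accuracy convention", {
  diag3 <- severity_confusion(
    rep(c("low", "moderate", "high"), c(2, 3, 4)),
    rep(c("low", "moderate", "high"), c(2, 3, 4))
  )
  cmx <- class_metrics(diag3)
  expect_true(all(cmx$sensitivity == 100))
  expect_true(all(cmx$precision == 100))
  expect_true(all(cmx$accuracy == cmx$sensitivity))
  expect_error(class_metrics(severity_confusion(character(0), character(0))), "empty")
  # never-predicted classes are dropped from macro precision with a warning
  skew <- severity_confusion(
    rep("moderate", 6), rep(c("low", "moderate", "high"), each = 2)
  )
  expect_warning(cm_skew <- class_metrics(skew), "never predicted")
  expect_equal(cm_skew$precision[cm_skew$class == "macro"], 100 * 2 / 6)
})
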