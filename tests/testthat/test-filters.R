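test_that("local statistics match direct enumeration", {
  x <- matrix(1:9, 3, 3, byrow = TRUE)
  ls3 <- local_stats(x, 3)
  expect_equal(ls3$mean[2, 2], 5)
  expect_equal(ls3$median[2, 2], 5)
  expect_equal(ls3$var[2, 2], 60 / 9)

  const <- matrix(0.7, 6, 6)
  lsc <- local_stats(const, 3)
  # mean equals the constant to 1 ulp (summation order is compiler-dependent);
  # median and variance are exact by construction
  expect_equal(lsc$mean, const, tolerance = 1e-15)
  expect_true(all(lsc$median == 0.7))
  expect_true(all(lsc$var == 0))

  imp <- matrix(0, 5, 5)
  imp[3, 3] <- 1
  expect_equal(local_stats(imp, 3)$median[3, 3], 0)

  expect_error(local_stats(matrix(0, 2, 2), c(3, 3) * 3), "window")
  expect_error(local_stats(x, 2), "odd")
})

test_that("the noise-variance estimator recovers known Gaussian noise", {
  expect_equal(estimate_noise_variance(matrix(0.5, 32, 32)), 0)
  set.seed(21)
  img <- matrix(0.5 + rnorm(256^2, 0, 0.05), 256)
  est <- estimate_noise_variance(img, 3)
  expect_lt(abs(est - 0.0025) / 0.0025, 0.15)
  # explicit variance bypasses the estimator
  sp <- filter_spec("wiener", noise_variance = 0.123)
  expect_equal(aaaseg:::resolve_noise_variance(img, sp), 0.123)
})

test_that("average filter is a normalized linear smoother", {
  const <- image2d(matrix(0.42, 16, 16))
  expect_equal(unclass(apply_average(const)), unclass(const), ignore_attr = TRUE)

  imp <- matrix(0, 9, 9)
  imp[5, 5] <- 1
  out <- apply_average(image2d(imp))
  expect_equal(out[4:6, 4:6], matrix(1 / 9, 3, 3))
  expect_equal(sum(out), 1)

  # linearity inside [0, 1] (no clipping active)
  set.seed(4)
  X <- matrix(runif(64, 0, 1), 8)
  Y <- matrix(runif(64, 0, 1), 8)
  lhs <- apply_average(image2d(0.3 * X + 0.5 * Y))
  rhs <- 0.3 * unclass(apply_average(image2d(X))) + 0.5 * unclass(apply_average(image2d(Y)))
  expect_equal(unclass(lhs), rhs, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(filter_spec("average", kernel = matrix(1, 3, 3)), "sum to 1")
})

test_that("median filter removes impulses and preserves step edges", {
  salt <- matrix(0.2, 7, 7)
  salt[4, 4] <- 1
  expect_equal(unclass(apply_median(image2d(salt))), matrix(0.2, 7, 7), ignore_attr = TRUE)

  expect_equal(apply_median(image2d(matrix(1:9 / 10, 3, 3, byrow = TRUE)))[2, 2], 0.5)

  step <- matrix(rep(c(0, 1), each = 4 * 8), 8, 8)
  expect_equal(unclass(apply_median(image2d(step))), step, ignore_attr = TRUE)
})

test_that("Wiener and MMWF follow the local gain law", {
  # engineered window: center 0.8, mean exactly 0.5, population var exactly 0.04
  d <- sqrt(0.03234375)
  v <- c(rep(0.4625 - d, 4), rep(0.4625 + d, 4))
  x <- matrix(c(v[1:4], 0.8, v[5:8]), 3, 3)
  out <- apply_wiener(image2d(x), filter_spec("wiener", noise_variance = 0.01))
  expect_equal(out[2, 2], 0.5 + (0.03 / 0.04) * (0.8 - 0.5), tolerance = 1e-10)

  # sigma_n^2 = 0: both reduce to the identity
  set.seed(9)
  img <- image2d(matrix(runif(32 * 32), 32))
  expect_equal(unclass(apply_wiener(img, filter_spec("wiener", noise_variance = 0))),
    unclass(img),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_equal(unclass(apply_mmwf(img, filter_spec("mmwf", noise_variance = 0))),
    unclass(img),
    tolerance = 1e-12, ignore_attr = TRUE
  )

  # flat region with local variance below the noise floor collapses to the mean
  flat <- image2d(matrix(0.6, 8, 8))
  expect_equal(unclass(apply_wiener(flat, filter_spec("wiener", noise_variance = 0.01))),
    matrix(0.6, 8, 8), ignore_attr = TRUE)

  # where the window is symmetric (median = mean) the two filters agree
  sym <- matrix(c(0.2, 0.4, 0.2, 0.4, 0.3, 0.4, 0.2, 0.4, 0.2), 3, 3)
  w <- apply_wiener(image2d(sym), filter_spec("wiener", noise_variance = 0.005))
  m <- apply_mmwf(image2d(sym), filter_spec("mmwf", noise_variance = 0.005))
  expect_equal(w[2, 2], m[2, 2])
})

test_that("all four filters match a naive per-pixel double-loop oracle", {
  set.seed(31)
  x <- matrix(runif(32 * 32), 32)
  sn2 <- 0.004
  for (kind in c("average", "median", "wiener", "mmwf")) {
    sp <- filter_spec(kind, noise_variance = sn2)
    got <- apply_filter(image2d(x), sp)
    want <- naive_filter(x, kind, kernel = sp$kernel, sn2 = sn2)
    expect_equal(unclass(got), want, tolerance = 1e-10, label = kind, ignore_attr = TRUE)
  }
})

test_that("filters preserve constants, bound ranges, and differ on impulses", {
  const <- image2d(matrix(0.55, 12, 12))
  for (kind in c("average", "median", "wiener", "mmwf")) {
    sp <- filter_spec(kind, noise_variance = "estimate")
    expect_equal(unclass(apply_filter(const, sp)), unclass(const), label = kind, ignore_attr = TRUE)
  }
  salt <- matrix(0.2, 9, 9)
  salt[5, 5] <- 1
  simg <- image2d(salt)
  expect_equal(apply_median(simg)[5, 5], 0.2)
  # with the noise variance at/above the local variance the MMWF gain clamps
  # to zero and the impulse collapses to the local median
  expect_equal(apply_mmwf(simg, filter_spec("mmwf", noise_variance = 0.1))[5, 5], 0.2)
  # the average filter spreads the impulse instead of removing it
  expect_gt(apply_average(simg)[5, 4], 0.2)
  set.seed(14)
  r <- image2d(matrix(runif(24 * 24, 0.1, 0.9), 24))
  for (kind in c("average", "median")) {
    out <- apply_filter(r, filter_spec(kind))
    expect_gte(min(out), min(r))
    expect_lte(max(out), max(r))
  }
})
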