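# Four-filter denoising bank sharing one sliding-window engine: average
# (linear kernel smoothing), median, classical Wiener
#   out = muL + (sigmaL^2 - sigman^2) / sigmaL^2 * (I - muL),
# and the median-modified Wiener filter (MMWF), which is the Wiener update
# anchored at the local median mL instead of the local mean. All filters use
# symmetric (reflect) border padding; the Wiener gain is clamped to [0, 1].

#' Denoising filter specification
#'
#' @param kind one of `"average"`, `"median"`, `"wiener"`, `"mmwf"`.
#' @param window odd window extents (scalar or `c(h, w)`); the reference
#'   protocol does not state a kernel size, so the smallest standard 3x3
#'   window is the default.
#' @param kernel weighting kernel for the average filter (defaults to uniform
#'   over the window); must be nonnegative and sum to 1.
#' @param noise_variance known noise variance `sigma_n^2` for Wiener/MMWF, or
#'   `"estimate"` to use [estimate_noise_variance()] on the input.
#' @return an object of class `"filter_spec"`.
#' @export
filter_spec <- function(kind = c("average", "median", "wiener", "mmwf"),
                        window = c(3, 3), kernel = NULL,
                        noise_variance = "estimate") {
  kind <- match.arg(kind)
  if (length(window) == 1) window <- c(window, window)
  window <- as.integer(window)
  if (any(window < 1) || any(window %% 2 == 0))
    abort("filter_spec: window extents must be odd and >= 1")
  if (kind == "average") {
    if (is.null(kernel)) kernel <- matrix(1 / prod(window), window[1], window[2])
    if (any(kernel < 0) || abs(sum(kernel) - 1) > 1e-8)
      abort("filter_spec: kernel weights must be nonnegative and sum to 1")
  }
  if (is.numeric(noise_variance) && noise_variance < 0)
    abort("filter_spec: noise_variance must be >= 0")
  structure(list(
    kind = kind, window = window, kernel = kernel,
    noise_variance = noise_variance
  ), class = "filter_spec")
}

#' Sliding-window local statistics
#'
#' Per-pixel mean, median and population variance over an odd window with
#' symmetric (reflect) border padding — the muL, mL and sigmaL^2 entering the
#' Wiener and MMWF updates.
#'
#' @param image matrix or [image2d()].
#' @param window odd window extents (scalar or `c(h, w)`).
#' @return list of matrices `mean`, `median`, `var` (class `"local_stats"`).
#' @export
local_stats <- function(image, window = c(3, 3)) {
  if (length(window) == 1) window <- c(window, window)
  window <- as.integer(window)
  if (any(window %% 2 == 0)) abort("local_stats: window extents must be odd")
  x <- unclass(image)
  if (any(window > 2 * dim(x)))
    abort("local_stats: window larger than the padded image")
  out <- cpp_local_stats(x, window[1], window[2])
  class(out) <- "local_stats"
  out
}

#' Estimate the noise variance from local statistics
#'
#' The classical sliding-window Wiener convention: the mean over all pixels of
#' the local (population) window variance. In smooth regions the local
#' variance is dominated by noise, so the average is a serviceable global
#' `sigma_n^2` estimate; the small-window bias (a 3x3 window underestimates
#' the variance of white noise by a few percent) is accepted and documented.
#'
#' @inheritParams local_stats
#' @return scalar noise-variance estimate (>= 0).
#' @export
estimate_noise_variance <- function(image, window = c(3, 3)) {
  mean(local_stats(image, window)$var)
}

resolve_noise_variance <- function(image, spec) {
  if (identical(spec$noise_variance, "estimate")) {
    estimate_noise_variance(image, spec$window)
  } else {
    spec$noise_variance
  }
}

#' Apply a denoising filter
#'
#' Dispatches on `spec$kind`; `apply_average()`, `apply_median()`,
#' `apply_wiener()` and `apply_mmwf()` are the direct entry points. Outputs
#' are clipped to \[0, 1\] (the average and median filters cannot leave the
#' input range, so clipping only affects Wiener/MMWF).
#'
#' @param image an [image2d()] (or matrix in \[0, 1\]).
#' @param spec a [filter_spec()] of the matching kind.
#' @return filtered [image2d()].
#' @export
apply_filter <- function(image, spec) {
  switch(spec$kind,
    average = apply_average(image, spec),
    median = apply_median(image, spec),
    wiener = apply_wiener(image, spec),
    mmwf = apply_mmwf(image, spec)
  )
}

#' @rdname apply_filter
#' @export
apply_average <- function(image, spec = filter_spec("average")) {
  if (spec$kind != "average") abort("apply_average: spec$kind must be 'average'")
  out <- cpp_convolve_reflect(unclass(image), spec$kernel)
  rewrap(pmin(pmax(out, 0), 1), image, "image2d")
}

#' @rdname apply_filter
#' @export
apply_median <- function(image, spec = filter_spec("median")) {
  if (spec$kind != "median") abort("apply_median: spec$kind must be 'median'")
  rewrap(local_stats(image, spec$window)$median, image, "image2d")
}

wiener_core <- function(image, spec, anchor = c("mean", "median")) {
  anchor <- match.arg(anchor)
  x <- unclass(image)
  sn2 <- resolve_noise_variance(image, spec)
  ls <- local_stats(image, spec$window)
  ctr <- if (anchor == "mean") ls$mean else ls$median
  gain <- (ls$var - sn2) / pmax(ls$var, 1e-12)
  gain <- pmin(pmax(gain, 0), 1) # clamp: never amplify, never invert contrast
  out <- ctr + gain * (x - ctr)
  rewrap(pmin(pmax(out, 0), 1), image, "image2d")
}

#' @rdname apply_filter
#' @export
apply_wiener <- function(image, spec = filter_spec("wiener")) {
  if (spec$kind != "wiener") abort("apply_wiener: spec$kind must be 'wiener'")
  wiener_core(image, spec, "mean")
}

#' @rdname apply_filter
#' @export
apply_mmwf <- function(image, spec = filter_spec("mmwf")) {
  if (spec$kind != "mmwf") abort("apply_mmwf: spec$kind must be 'mmwf'")
  wiener_core(image, spec, "median")
}
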