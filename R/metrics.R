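# Segmentation-quality metrics: pixel-wise confusion counts, Matthews
# correlation (MCC), Dice (DSC), Jaccard (JC = DSC / (2 - DSC)), the
# one-directional mean surface distance (MSD), PSNR, ICC(2,1) inter-rater
# agreement, one-way ANOVA across filter arms and relative-improvement
# percentages.

#' Pixel-wise confusion counts between two binary masks
#'
#' Foreground (1) is the positive class.
#'
#' @param pred,truth same-shaped [binary_mask()] objects (or 0/1 matrices).
#' @return object of class `"confusion_counts"` with fields `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- unclass(pred)
  t <- unclass(truth)
  if (!all(dim(p) == dim(t))) abort("confusion_counts: shape mismatch")
  # doubles: pixel-count products overflow 32-bit integers in the MCC
  structure(list(
    tp = as.numeric(sum(p == 1 & t == 1)), tn = as.numeric(sum(p == 0 & t == 0)),
    fp = as.numeric(sum(p == 1 & t == 0)), fn = as.numeric(sum(p == 0 & t == 1))
  ), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in \[-1, 1\].
#' When any denominator factor is zero (e.g. an all-background prediction)
#' the MCC is defined as 0 so aggregate means stay well defined.
#'
#' @param counts a [confusion_counts()] object.
#' @export
mcc <- function(counts) {
  c_ <- counts
  den <- (c_$tp + c_$fp) * (c_$tp + c_$fn) * (c_$tn + c_$fp) * (c_$tn + c_$fn)
  if (den == 0) return(0)
  (c_$tp * c_$tn - c_$fp * c_$fn) / sqrt(den)
}

#' Dice similarity coefficient
#'
#' `2TP / (2TP + FP + FN)`; equals the harmonic mean of precision and
#' sensitivity. Two empty masks give DSC = 1 by convention.
#'
#' @param counts a [confusion_counts()] object.
#' @export
dsc <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(1)
  2 * counts$tp / den
}

#' Jaccard coefficient from a Dice value
#'
#' `JC = DSC / (2 - DSC)`, algebraically identical to the set-based
#' intersection-over-union `TP / (TP + FP + FN)`.
#'
#' @param dsc_value Dice value in \[0, 1\].
#' @export
jc <- function(dsc_value) {
  if (any(dsc_value < 0 | dsc_value > 1)) abort("jc: DSC must lie in [0, 1]")
  dsc_value / (2 - dsc_value)
}

mask_coords <- function(mask) {
  which(unclass(mask) == 1, arr.ind = TRUE)
}

#' Mean surface distance
#'
#' Implemented literally as stated for this pipeline: the mean, over the
#' pixels of the predicted (segmented) foreground, of the Euclidean distance
#' to the nearest ground-truth foreground pixel. This is one-directional and
#' therefore not symmetric under swapping `pred` and `truth`. A symmetric
#' boundary-based variant (average of both directed boundary means) is
#' available behind `symmetric = TRUE`.
#'
#' @param pred,truth binary masks; `truth` must have foreground, and an empty
#'   prediction is an error (MSD is undefined — callers that aggregate should
#'   catch and flag it).
#' @param spacing_mm optional pixel spacing; when given, the result is in mm
#'   instead of pixels.
#' @param symmetric use the symmetric boundary variant?
#' @export
msd <- function(pred, truth, spacing_mm = NULL, symmetric = FALSE) {
  if (sum(unclass(truth) == 1) == 0) abort("msd: truth mask has no foreground")
  if (sum(unclass(pred) == 1) == 0) abort("msd: empty prediction, MSD undefined")
  if (symmetric) {
    pb <- mask_coords(edge_map(pred))
    tb <- mask_coords(edge_map(truth))
    d <- (mean(cpp_nearest_dist(pb, tb)) + mean(cpp_nearest_dist(tb, pb))) / 2
  } else {
    d <- mean(cpp_nearest_dist(mask_coords(pred), mask_coords(truth)))
  }
  if (!is.null(spacing_mm)) d <- d * spacing_mm
  d
}

#' Peak signal-to-noise ratio from an MSE
#'
#' `10 * log10(peak^2 / mse)`; with intensities normalized to \[0, 1\] the
#' peak is 1.
#'
#' @param mse mean squared error (> 0; a zero MSE would be infinite PSNR and
#'   is an error here).
#' @param peak peak signal value.
#' @export
psnr <- function(mse, peak = 1) {
  if (any(mse <= 0)) abort("psnr: mse must be > 0 (zero MSE = infinite PSNR)")
  10 * log10(peak^2 / mse)
}

#' Evaluate predicted masks against ground truth
#'
#' @param pred,truth lists of same-shaped binary masks, paired by position.
#' @param id optional identifiers (defaults to positions).
#' @param spacing_mm optional spacing for MSD in mm.
#' @return tibble with one row per image: `id`, `mcc`, `dsc`, `jc`, `msd`
#'   (`msd` is `NA` with a warning for empty predictions).
#' @export
evaluate_masks <- function(pred, truth, id = NULL, spacing_mm = NULL) {
  stopifnot(length(pred) == length(truth))
  id <- id %||% seq_along(pred)
  purrr::map_dfr(seq_along(pred), function(i) {
    cc <- confusion_counts(pred[[i]], truth[[i]])
    d <- dsc(cc)
    m <- tryCatch(msd(pred[[i]], truth[[i]], spacing_mm = spacing_mm),
      error = function(e) {
        warn(sprintf("image %s: %s", as.character(id[i]), conditionMessage(e)))
        NA_real_
      }
    )
    tibble::tibble(id = id[i], mcc = mcc(cc), dsc = d, jc = jc(d), msd = m)
  })
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' standard mean-squares decomposition, with the usual F-based confidence
#' interval. Used to quantify agreement between independent annotators.
#'
#' @param ratings numeric matrix, n subjects x k raters, no missing cells.
#' @param conf confidence level for the interval (default 0.95).
#' @return object of class `"aaa_icc"`: list with `icc`, `ci` (length 2),
#'   `ms` (mean squares), `n`, `k`.
#' @export
icc_2_1 <- function(ratings, conf = 0.95) {
  x <- as.matrix(ratings)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) abort("icc_2_1: need >= 2 subjects and >= 2 raters")
  if (any(!is.finite(x))) abort("icc_2_1: missing cells are not supported")
  gm <- mean(x)
  sst <- sum((x - gm)^2)
  if (sst == 0) abort("icc_2_1: zero total variance")
  ssr <- k * sum((rowMeans(x) - gm)^2)
  ssc <- n * sum((colMeans(x) - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) * (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fu <- qf(1 - alpha / 2, n - 1, v)
  fl <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fu * mse) /
    (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fl * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fl * msr)
  structure(list(
    icc = icc, ci = c(lower = lower, upper = upper), conf = conf,
    ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k
  ), class = "aaa_icc")
}

#' @export
print.aaa_icc <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.3f (%d%% CI %.3f-%.3f; n = %d subjects, k = %d raters)\n",
    x$icc, round(100 * x$conf), x$ci[1], x$ci[2], x$n, x$k
  ))
  invisible(x)
}

#' @method tidy aaa_icc
#' @export
tidy.aaa_icc <- function(x, ...) {
  tibble::tibble(
    estimate = x$icc, conf.low = x$ci[[1]], conf.high = x$ci[[2]],
    n_subjects = x$n, n_raters = x$k
  )
}

#' One-way analysis of variance
#'
#' Classical between/within mean-squares F test, used to compare per-slice
#' segmentation metrics across filter arms. The fully degenerate case (all
#' group means equal and zero within-group variance) is defined as F = 0,
#' p = 1.
#'
#' @param x either a list of numeric vectors (one per group) or a data frame
#'   holding the value and group columns named below.
#' @param value,group column names when `x` is a data frame.
#' @return object of class `"aaa_anova"` with `tidy()` and `glance()` methods.
#' @export
one_way_anova <- function(x, value = "value", group = "group") {
  if (is.data.frame(x)) {
    x <- split(x[[value]], x[[group]])
  }
  if (length(x) < 2) abort("one_way_anova: need >= 2 groups")
  sizes <- lengths(x)
  if (any(sizes < 2)) abort("one_way_anova: every group needs >= 2 values")
  all_v <- unlist(x, use.names = FALSE)
  gm <- mean(all_v)
  means <- vapply(x, mean, 0)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum(vapply(seq_along(x), function(i) sum((x[[i]] - means[i])^2), 0))
  df <- c(between = length(x) - 1, within = length(all_v) - length(x))
  msb <- ssb / df[1]
  msw <- ssw / df[2]
  if (msw == 0 && msb == 0) {
    f <- 0
    p <- 1
  } else if (msw == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- msb / msw
    p <- pf(f, df[1], df[2], lower.tail = FALSE)
  }
  structure(list(
    statistic = unname(f), df = unname(df), p.value = unname(p),
    sumsq = c(between = ssb, within = ssw),
    meansq = c(between = msb, within = msw),
    n_groups = length(x), n_total = length(all_v)
  ), class = "aaa_anova")
}

#' @export
print.aaa_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
    x$df[1], x$df[2], x$statistic, x$p.value
  ))
  invisible(x)
}

#' @method tidy aaa_anova
#' @export
tidy.aaa_anova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = x$df, sumsq = unname(x$sumsq), meansq = unname(x$meansq),
    statistic = c(x$statistic, NA), p.value = c(x$p.value, NA)
  )
}

#' @method glance aaa_anova
#' @export
glance.aaa_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df_between = x$df[1], df_within = x$df[2],
    p.value = x$p.value
  )
}

#' Relative improvement between two metric values, in percent
#'
#' Three conventions cover the ways improvements are quoted: relative to the
#' baseline (`(after - before) / before * 100`, used for scores that
#' increase), relative to the improved value
#' (`(before - after) / after * 100`, used for the mean surface distance
#' where improvement is a decrease), and plain percentage-point difference
#' (`after - before`).
#'
#' @param before,after the two values being compared.
#' @param mode one of `"relative_to_before"`, `"relative_to_after"`,
#'   `"difference"`.
#' @return percentage (or percentage points for `"difference"`).
#' @export
relative_improvement <- function(before, after,
                                 mode = c(
                                   "relative_to_before", "relative_to_after",
                                   "difference"
                                 )) {
  mode <- match.arg(mode)
  switch(mode,
    relative_to_before = {
      if (before == 0) abort("relative_improvement: zero denominator")
      (after - before) / before * 100
    },
    relative_to_after = {
      if (after == 0) abort("relative_improvement: zero denominator")
      (before - after) / after * 100
    },
    difference = after - before
  )
}
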