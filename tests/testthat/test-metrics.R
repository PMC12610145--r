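test_that("confusion counts agree with an exhaustive pixel loop", {
  t_ <- binary_mask(matrix(c(rep(1, 10), rep(0, 90)), 10, 10))
  cc <- confusion_counts(t_, t_)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")], list(tp = 10, tn = 90, fp = 0, fn = 0))
  comp <- binary_mask(1 - unclass(t_))
  cc2 <- confusion_counts(comp, t_)
  expect_equal(cc2$tp + cc2$tn, 0)

  set.seed(2)
  for (rep in 1:5) {
    p <- random_mask(8)
    t2 <- random_mask(8)
    cc3 <- confusion_counts(p, t2)
    tp <- tn <- fp <- fn <- 0
    for (i in 1:8) {
      for (j in 1:8) {
        if (p[i, j] == 1 && t2[i, j] == 1) tp <- tp + 1
        if (p[i, j] == 0 && t2[i, j] == 0) tn <- tn + 1
        if (p[i, j] == 1 && t2[i, j] == 0) fp <- fp + 1
        if (p[i, j] == 0 && t2[i, j] == 1) fn <- fn + 1
      }
    }
    expect_equal(unname(unlist(unclass(cc3))), c(tp, tn, fp, fn))
  }
  expect_error(confusion_counts(random_mask(4), random_mask(5)), "shape")
})

test_that("MCC, DSC and JC follow their closed forms and conventions", {
  perfect <- confusion_counts(make_disk_mask(16, 4), make_disk_mask(16, 4))
  expect_equal(mcc(perfect), 1)
  expect_equal(dsc(perfect), 1)

  cc <- structure(list(tp = 2, tn = 2, fp = 1, fn = 1), class = "confusion_counts")
  expect_equal(mcc(cc), 3 / 9)
  cc2 <- structure(list(tp = 12, tn = 0, fp = 1, fn = 2), class = "confusion_counts")
  expect_equal(dsc(cc2), 24 / 27)
  expect_equal(jc(dsc(cc2)), 12 / 15)

  # all-background prediction on mixed truth: zero factor -> MCC 0 by convention
  allbg <- confusion_counts(
    binary_mask(matrix(0, 4, 4)),
    binary_mask(matrix(c(1, rep(0, 15)), 4, 4))
  )
  expect_equal(mcc(allbg), 0)
  # two empty masks: DSC 1 by convention
  empty <- confusion_counts(binary_mask(matrix(0, 3, 3)), binary_mask(matrix(0, 3, 3)))
  expect_equal(dsc(empty), 1)
  expect_equal(jc(1), 1)
  expect_equal(jc(0), 0)

  # identity JC = TP/(TP+FP+FN) over random counts
  set.seed(8)
  for (r in 1:20) {
    k <- as.list(sample(0:30, 4, replace = TRUE))
    names(k) <- c("tp", "tn", "fp", "fn")
    if (k$tp + k$fp + k$fn == 0) next
    cc4 <- structure(k, class = "confusion_counts")
    expect_equal(jc(dsc(cc4)), k$tp / (k$tp + k$fp + k$fn))
  }

  # symmetry: MCC and DSC invariant under swapping prediction and truth
  set.seed(12)
  a <- random_mask(8)
  b <- random_mask(8)
  expect_equal(mcc(confusion_counts(a, b)), mcc(confusion_counts(b, a)))
  expect_equal(dsc(confusion_counts(a, b)), dsc(confusion_counts(b, a)))
})

test_that("mean surface distance is the literal one-directional average", {
  m <- make_disk_mask(16, 4)
  expect_equal(msd(m, m), 0)

  p <- binary_mask(matrix(c(1, rep(0, 255)), 16, 16)) # pixel (1,1)
  t_ <- binary_mask(matrix(c(rep(0, 4), 1, rep(0, 251)), 16, 16)) # pixel (5,1)
  expect_equal(msd(p, t_), 4)

  # brute-force all-pairs oracle on random masks
  set.seed(3)
  for (r in 1:5) {
    pr <- random_mask(16, 0.2)
    tr <- random_mask(16, 0.2)
    if (sum(pr == 1) == 0 || sum(tr == 1) == 0) next
    pc <- which(unclass(pr) == 1, arr.ind = TRUE)
    tc <- which(unclass(tr) == 1, arr.ind = TRUE)
    oracle <- mean(apply(pc, 1, function(q) {
      min(sqrt((q[1] - tc[, 1])^2 + (q[2] - tc[, 2])^2))
    }))
    expect_equal(msd(pr, tr), oracle)
    # one-directional: generally not symmetric
  }
  a <- binary_mask(matrix(c(1, 1, rep(0, 14)), 4, 4))
  b <- binary_mask(matrix(c(1, rep(0, 15)), 4, 4))
  expect_false(isTRUE(all.equal(msd(a, b), msd(b, a))))

  expect_equal(msd(p, t_, spacing_mm = 1.5), 6)
  expect_error(msd(binary_mask(matrix(0, 4, 4)), t_), "empty prediction")
  expect_error(msd(p, binary_mask(matrix(0, 16, 16))), "no foreground")
})

test_that("PSNR follows 10*log10(peak^2/mse)", {
  expect_equal(psnr(0.01), 20)
  expect_equal(psnr(0.25, peak = 0.5), 0)
  expect_equal(psnr(0.02) - psnr(0.04), 10 * log10(2))
  expect_error(psnr(0), "> 0")
})

test_that("ICC(2,1) matches its mean-squares definition and recovers simulations", {
  # raters identical on varying subjects -> perfect agreement
  x <- cbind(1:6, 1:6, 1:6)
  r <- icc_2_1(x)
  expect_equal(r$icc, 1)

  expect_error(icc_2_1(matrix(1:5, 5, 1)), "raters")
  expect_error(icc_2_1(matrix(3, 4, 3)), "variance")

  # cross-check the mean squares against an independent two-way lm fit
  set.seed(6)
  y <- matrix(rnorm(12 * 3), 12, 3) + rnorm(12)
  fit <- stats::lm(as.vector(y) ~ factor(rep(1:12, 3)) + factor(rep(1:3, each = 12)))
  an <- stats::anova(fit)
  r2 <- icc_2_1(y)
  expect_equal(unname(r2$ms["msr"]), an$`Mean Sq`[1])
  expect_equal(unname(r2$ms["msc"]), an$`Mean Sq`[2])
  expect_equal(unname(r2$ms["mse"]), an$`Mean Sq`[3])

  # parameter recovery: var(subject) / (var(subject) + var(noise)) = 0.8
  set.seed(77)
  n <- 500
  subj <- rnorm(n, sd = 1)
  ratings <- sapply(1:3, function(k) subj + rnorm(n, sd = 0.5))
  r3 <- icc_2_1(ratings)
  expect_lt(abs(r3$icc - 0.8), 0.05)
  expect_true(r3$ci[1] < r3$icc && r3$icc < r3$ci[2])
})

test_that("one-way ANOVA matches the classical F statistic", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$statistic, 3)
  expect_equal(a$df, c(2, 6))
  # independent route: stats::oneway.test with pooled variance
  d <- data.frame(
    value = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    group = rep(c("a", "b", "c"), each = 3)
  )
  ref <- stats::oneway.test(value ~ group, d, var.equal = TRUE)
  expect_equal(a$statistic, unname(ref$statistic))
  expect_equal(a$p.value, unname(ref$p.value))

  # data-frame interface and shift invariance
  a2 <- one_way_anova(d)
  expect_equal(a2$statistic, a$statistic)
  d$value <- d$value + 100
  expect_equal(one_way_anova(d)$statistic, a$statistic)

  deg <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p.value, 1)
  expect_error(one_way_anova(list(c(1, 2), numeric(0))), ">= 2")

  td <- tidy(a)
  expect_equal(td$df, c(2, 6))
  expect_equal(glance(a)$p.value, a$p.value)
})

test_that("relative improvement handles all three conventions", {
  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_equal(relative_improvement(0.5, 0.6), 20)
  expect_equal(relative_improvement(90, 80, "relative_to_after"), 12.5)
  expect_equal(relative_improvement(70, 90, "difference"), 20)
  expect_error(relative_improvement(0, 1), "denominator")
  expect_error(relative_improvement(1, 0, "relative_to_after"), "denominator")
})
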