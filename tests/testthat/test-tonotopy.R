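mkClass <- function(bfs, labels = rep("single", length(bfs))) {
  data.frame(neuron_id = paste0("n", seq_along(bfs)), is_sensitive = TRUE,
             label = labels, bf_hz = bfs)
}

test_that("local deviation uses a leave-one-out centre in octaves", {
  d <- localBFDeviation(mkClass(c(1000, 1000, 1000, 8000)), extent_mm = 0.25)
  # the 8 kHz outlier is 3 octaves from the median (1 kHz) of the others
  expect_equal(d$deviation_oct[4], 3)
  expect_equal(d$deviation_oct_per_mm[4], 3 / 0.25)
  # all equal BFs give zero deviation
  expect_true(all(localBFDeviation(mkClass(rep(2000, 5)),
                                   0.25)$deviation_oct == 0))
})

test_that("local deviation matches a direct leave-one-out oracle", {
  set.seed(17)
  for (center in c("median", "mean")) {
    bfs <- 1000 * 2^runif(9, 0, 4)
    labels <- sample(c("single", "double"), 9, replace = TRUE, c(0.6, 0.4))
    d <- localBFDeviation(mkClass(bfs, labels), 0.3, reference = "same_class",
                          center = center)
    cfun <- if (center == "median") median else mean
    for (i in seq_len(nrow(d))) {
      j <- match(d$neuron_id[i], paste0("n", 1:9))
      others <- bfs[labels == labels[j] & seq_along(bfs) != j]
      expect_equal(d$deviation_oct[i],
                   abs(log2(bfs[j]) - cfun(log2(others))), tolerance = 1e-12)
    }
  }
})

test_that("classes below the inclusion minimum are excluded", {
  cl <- mkClass(c(1000, 2000, 4000, 8000, 500),
                c("single", "single", "single", "double", "double"))
  d <- localBFDeviation(cl, 0.25)
  expect_equal(sort(unique(d$label)), "single")
  expect_equal(attr(d, "excluded_classes"), "double")
})

test_that("mean and median centres coincide on log-symmetric reference sets", {
  # leave-one-out centres only see a symmetric set for the centre neuron
  bfs <- 1000 * 2^c(-1, -0.5, 0, 0.5, 1)
  dm <- localBFDeviation(mkClass(bfs), 0.25, center = "median")
  da <- localBFDeviation(mkClass(bfs), 0.25, center = "mean")
  expect_equal(dm$deviation_oct[3], da$deviation_oct[3], tolerance = 1e-12)
  expect_equal(dm$deviation_oct[3], 0)
  # and everywhere when the field is flat on the log scale
  flat <- localBFDeviation(mkClass(rep(4000, 6)), 0.25, center = "mean")
  expect_true(all(flat$deviation_oct == 0))
})

test_that("species slopes reproduce the published octave-per-mm values", {
  expect_equal(round(speciesSlope(2000, 60000, 1.0), 2), 4.91)
  expect_equal(round(speciesSlope(36, 44000, 3.5), 2), 2.93)
  expect_equal(speciesSlope(3000, 6000, 1.0), 1.0)
})

test_that("expected-range fraction counts BFs within the gradient span", {
  expect_equal(expectedRangeFraction(rep(3000, 7), 4.91, 0.3), 100)
  # mouse preset, 0.3 mm field: half-width 0.7365 oct, a 2-octave outlier
  # falls outside
  bfs <- c(4000, 4500, 5000, 4000 * 2^2)
  half <- 4.91 * 0.3 / 2
  dev <- abs(log2(bfs) - median(log2(bfs)))
  expect_equal(expectedRangeFraction(bfs, 4.91, 0.3),
               100 * sum(dev <= half) / 4)
  expect_lt(expectedRangeFraction(bfs, 4.91, 0.3), 100)
  # counting oracle on random draws, and invariance to octave translation
  set.seed(3)
  for (k in 1:20) {
    b <- 1000 * 2^runif(12, 0, 5)
    got <- expectedRangeFraction(b, 2.93, 0.25)
    oracle <- 100 * mean(abs(log2(b) - median(log2(b))) <= 2.93 * 0.25 / 2)
    expect_equal(got, oracle)
    expect_equal(expectedRangeFraction(3.7 * b, 2.93, 0.25), got)
  }
  expect_true(is.na(expectedRangeFraction(numeric(0), 2.93, 0.25)))
})

test_that("equal-n bootstrap is reproducible and degenerates to the full estimate", {
  flds <- lapply(1:3, function(k)
    generateField("ferret", n_neurons = 40, seed = k,
                  class_mix = sensitiveOnlyMix()))
  cls <- lapply(flds, classifyNeurons)
  ext <- vapply(flds, fieldExtentMm, numeric(1))
  b1 <- equalNBootstrap(cls, ext, n_per_class = 3, n_boot = 20, seed = 9)
  b2 <- equalNBootstrap(cls, ext, n_per_class = 3, n_boot = 20, seed = 9)
  expect_identical(b1$draws, b2$draws)
  # drawing the full class size reproduces the non-bootstrap estimate
  n_single <- min(vapply(cls, function(cl)
    sum(cl$label == "single", na.rm = TRUE), integer(1)))
  cls_trim <- lapply(cls, function(cl) {
    idx <- which(cl$is_sensitive & !is.na(cl$label) & cl$label == "single")
    cl[idx[seq_len(n_single)], , drop = FALSE]
  })
  bfull <- equalNBootstrap(cls_trim, ext, n_per_class = n_single,
                           n_boot = 5, seed = 2, classes = "single")
  direct <- mean(unlist(Map(function(cl, e)
    localBFDeviation(cl, e)$deviation_oct, cls_trim, ext)))
  expect_equal(unname(bfull$draws[, "single"]), rep(direct, 5),
               tolerance = 1e-12)
})

test_that("increasing generative scatter increases mean local deviation", {
  devs <- vapply(c(0.2, 0.6, 1.2), function(sc) {
    fld <- generateField("ferret", n_neurons = 50, seed = 77,
                         class_mix = c(1, 0, 0, 0),
                         bf_scatter_oct = c(single = sc, double = 0.7,
                                            complex = 1.2))
    cl <- classifyNeurons(fld)
    mean(localBFDeviation(cl, fieldExtentMm(fld))$deviation_oct)
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
})

test_that("the exponential gradient fit recovers exact and noisy maps", {
  x <- seq(0, 3, length.out = 40)
  bf <- 500 * 2^(2.5 * x)
  fit <- fitGlobalGradient(x, bf)
  expect_equal(abs(fit$pearson_r), 1, tolerance = 1e-9)
  expect_equal(fit$slope_oct_per_mm, 2.5, tolerance = 1e-9)
  expect_true(all(fit$residuals_oct < 1e-9))
  # a, b parameterize BF = a * exp(b x)
  expect_equal(fit$a * exp(fit$b * 1.7), 500 * 2^(2.5 * 1.7),
               tolerance = 1e-6)
  # reversing the axis flips the sign of slope and correlation
  rev_fit <- fitGlobalGradient(max(x) - x, bf)
  expect_equal(rev_fit$slope_oct_per_mm, -2.5, tolerance = 1e-9)
  expect_equal(rev_fit$pearson_r, -fit$pearson_r, tolerance = 1e-9)
  # parameter recovery under scatter
  set.seed(12)
  xx <- runif(500, 0, 3.5)
  bfn <- 36 * 2^(2.9 * xx + rnorm(500, 0, 0.3))
  fitn <- fitGlobalGradient(xx, bfn)
  expect_lt(abs(fitn$slope_oct_per_mm - 2.9) / 2.9, 0.05)
  # degenerate inputs flagged
  expect_true(fitGlobalGradient(rep(1, 5), c(1, 2, 4, 8, 16) * 100)$degenerate)
  expect_error(fitGlobalGradient(1:2, c(100, 200)), "at least 3")
})

test_that("residual comparisons reproduce the Welch t-test", {
  set.seed(21)
  res <- c(abs(rnorm(30, 1)), abs(rnorm(25, 1)))
  lab <- rep(c("single", "double"), c(30, 25))
  out <- compareResiduals(res, lab)
  ref <- t.test(res[lab == "double"], res[lab == "single"])
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p, ref$p.value)
  # identical groups: t ~ 0, p ~ 1
  same <- compareResiduals(c(1, 2, 3, 1, 2, 3),
                           rep(c("single", "double"), each = 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # well-separated groups
  sep <- compareResiduals(c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)),
                          rep(c("a", "b"), each = 20))
  expect_lt(sep$p, 1e-6)
})
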