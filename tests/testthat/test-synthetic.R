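test_that("identical seeds and configs produce identical fields", {
  a <- generateField("ferret", n_neurons = 15, seed = 7)
  b <- generateField("ferret", n_neurons = 15, seed = 7)
  expect_identical(SummarizedExperiment::assay(a, "responses"),
                   SummarizedExperiment::assay(b, "responses"))
  expect_identical(as.data.frame(SummarizedExperiment::rowData(a)),
                   as.data.frame(SummarizedExperiment::rowData(b)))
  c <- generateField("ferret", n_neurons = 15, seed = 8)
  expect_false(identical(SummarizedExperiment::assay(a, "responses"),
                         SummarizedExperiment::assay(c, "responses")))
})

test_that("responses are nonnegative with shapes matching the grid", {
  fld <- generateField("mouse", n_neurons = 12, seed = 3)
  g <- stimulusGrid(fld)
  resp <- SummarizedExperiment::assay(fld, "responses")
  expect_true(all(resp >= 0))
  expect_equal(ncol(resp),
               length(frequencies(g)) * length(soundLevels(g)) * nTrials(g))
  tens <- responseTensor(fld, 1)
  expect_equal(dim(tens),
               c(length(frequencies(g)), length(soundLevels(g)), nTrials(g)))
})

test_that("class assignment follows the multinomial mixture", {
  mix <- sensitiveOnlyMix()
  g <- tinyGrid(n_freq = 9, n_level = 2, n_trial = 4)
  fld <- generateField("ferret", grid = g, n_neurons = 10000, seed = 21,
                       class_mix = mix)
  counts <- table(factor(groundTruth(fld)$true_class, names(mix)))
  for (cls in names(mix)) {
    expected <- 10000 * mix[[cls]]
    sd3 <- 3 * sqrt(10000 * mix[[cls]] * (1 - mix[[cls]]))
    expect_lt(abs(counts[[cls]] - expected), max(sd3, 1))
  }
  expect_error(generateField("ferret", n_neurons = 10,
                             class_mix = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(generateField("ferret", n_neurons = 0), "n_neurons")
})

test_that("neuropil mixing with c = 0 is the identity and follows the mixing formula", {
  own <- generateField("ferret", n_neurons = 10, seed = 13,
                       neuropil_coeff = 0)
  mixed <- generateField("ferret", n_neurons = 10, seed = 13,
                         neuropil_coeff = 0.4)
  r_own <- SummarizedExperiment::assay(own, "responses")
  r_mix <- SummarizedExperiment::assay(mixed, "responses")
  expect_null(S4Vectors::metadata(own)$neuropil)
  npil <- S4Vectors::metadata(mixed)$neuropil
  expect_equal(npil, unname(colMeans(r_own)), tolerance = 1e-12)
  expect_equal(r_mix,
               0.6 * r_own + 0.4 * matrix(npil, 10, ncol(r_own), byrow = TRUE),
               tolerance = 1e-12)
})

test_that("shared-noise loading yields the analytic noise correlation", {
  # two single-peaked neurons, loading L = 0.6, sd_shared 0.1, sd_ind 0.15;
  # expected rho = L^2 s_c^2 / (L^2 s_c^2 + s^2); baseline keeps the noise
  # clear of the rectifier
  g <- StimulusGrid(c(1000, 2000), 50, n_trials = 5000)
  fld <- generateField("ferret", grid = g, n_neurons = 2, seed = 99,
                       class_mix = c(1, 0, 0, 0),
                       bf_scatter_oct = c(single = 0, double = 0, complex = 0),
                       noise = list(baseline = 5))
  rho <- (0.6^2 * 0.1^2) / (0.6^2 * 0.1^2 + 0.15^2)
  r <- noiseCorrelation(responseTensor(fld, 1), responseTensor(fld, 2))
  expect_lt(abs(as.numeric(r) - rho), 0.02)
})

test_that("the FRA template peaks at BF and realizes the requested shape", {
  g <- ferretGrid()
  f <- frequencies(g)
  tpl <- fraTemplate("single", 8000, 0.5, g)
  i_near <- which.min(abs(log2(f / 8000)))
  for (j in seq_along(soundLevels(g)))
    expect_equal(unname(which.max(tpl[, j])), i_near)
  # global maximum at (BF, highest level)
  expect_equal(unname(which(tpl == max(tpl), arr.ind = TRUE)[1, ]),
               c(i_near, length(soundLevels(g))))
  expect_true(all(tpl >= 0))

  # double: exactly two suprathreshold regions in the level-averaged profile
  tpl2 <- fraTemplate("double", 2000, 0.5, g, peak2_hz = 16000,
                      peak2_gain_ratio = 0.8)
  prof <- rowMeans(tpl2)
  expect_equal(regionCount(prof, 0.75 * max(prof)), 2L)

  # template bandwidth is recovered by the bandwidth operation
  fine <- StimulusGrid(1000 * 2^seq(0, 3, by = 0.05), 60, n_trials = 2)
  tpl3 <- fraTemplate("single", 2828, 0.5, fine, widen_per_db = 0)
  prof3 <- rowMeans(tpl3)
  bf <- bestFrequency(prof3, frequencies(fine))
  # agreement to within one grid step (0.05 oct) per side
  expect_lt(abs(bandwidthOct(prof3, bf, frequencies(fine)) - 0.5), 0.101)

  expect_error(fraTemplate("single", 8000, 0.5, g, peak2_hz = 1000),
               "double")
  expect_error(fraTemplate("double", 8000, 0.5, g), "requires")
  expect_error(fraTemplate("single", 100, 0.5, g), "range")
  expect_true(all(fraTemplate("nonsensitive", 8000, 0.5, g) == 0))
})

test_that("calcium convolution is linear with the indicator half-decay", {
  expect_equal(convolveCalcium(rep(0, 50), "GCaMP6f"), rep(0, 50))
  dt <- 0.1
  imp <- c(1, rep(0, 99))
  tr <- convolveCalcium(imp, "GCaMP6f", dt = dt)
  # value half-decays over 0.7 time units = 7 samples
  expect_equal(tr[8] / tr[1], 0.5, tolerance = 1e-6)
  tr_m <- convolveCalcium(imp, "GCaMP6m", dt = dt)
  expect_equal(tr_m[13] / tr_m[1], 0.5^(1.2 / 1.25), tolerance = 1e-6)
  # kernel integrates to the requested gain
  expect_equal(sum(convolveCalcium(c(1, rep(0, 500)), "GCaMP6f", gain = 2.5)),
               2.5, tolerance = 1e-6)
  # superposition of two impulses
  e1 <- c(1, rep(0, 59)); e2 <- c(rep(0, 20), 1, rep(0, 39))
  expect_equal(convolveCalcium(e1 + e2, "GCaMP6f"),
               convolveCalcium(e1, "GCaMP6f") + convolveCalcium(e2, "GCaMP6f"),
               tolerance = 1e-9)
  expect_error(convolveCalcium(1:3, "GCaMP7"), "'arg' should be one of")
})

test_that("noiseless zero-scatter fields are exactly recovered downstream", {
  fld <- generateField("ferret", n_neurons = 30, seed = 4,
                       class_mix = c(0.4, 0.3, 0.3, 0),
                       bf_scatter_oct = c(single = 0, double = 0, complex = 0),
                       noise = list(sd_independent = 0, sd_shared = 0))
  cl <- classifyNeurons(fld)
  gt <- groundTruth(fld)
  expect_true(all(cl$is_sensitive))
  expect_identical(cl$label, gt$true_class)
  f <- frequencies(stimulusGrid(fld))
  nearest <- vapply(gt$true_bf_hz,
                    function(b) f[which.min(abs(log2(f / b)))], numeric(1))
  expect_equal(cl$bf_hz, nearest)
  # the noiseless double-peaked neurons also recover peak 2 exactly
  dbl <- which(gt$true_class == "double")
  expect_equal(cl$peak2_hz[dbl], gt$true_peak2_hz[dbl])
})
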