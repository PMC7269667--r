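test_that("evoked activity averages the response window", {
  expect_equal(evokedActivity(rep(0, 100), onset = 10, stim_duration = 20), 0)
  expect_equal(evokedActivity(rep(3.7, 100), onset = 10, stim_duration = 20),
               3.7)
  # ramp trace: direct-sum oracle over the window [onset, onset + 2*dur)
  tr <- seq_len(100)
  win <- 11:50
  expect_equal(evokedActivity(tr, onset = 10, stim_duration = 20),
               sum(tr[win]) / length(win))
  expect_error(evokedActivity(rep(0, 30), onset = 10, stim_duration = 20),
               "window")
})

test_that("two-way ANOVA F decomposition matches hand-computed sums of squares", {
  set.seed(5)
  d <- c(2, 2, 3)  # freq x level x trial
  resp <- array(rnorm(prod(d), mean = 2, sd = 1), dim = d)
  resp[2, , ] <- resp[2, , ] + 1.5
  out <- frequencySensitivity(resp)

  # balanced type-I decomposition from scratch
  x <- as.vector(resp)
  fr <- rep(rep(1:2, 2), 3); lv <- rep(rep(1:2, each = 2), 3)
  gm <- mean(x)
  ss_f <- sum(tapply(x, fr, function(v) length(v) * (mean(v) - gm)^2))
  ss_l <- sum(tapply(x, lv, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(x, interaction(fr, lv), mean)
  ss_cells <- sum(3 * (cellm - gm)^2)
  ss_int <- ss_cells - ss_f - ss_l
  ss_res <- sum((x - ave(x, interaction(fr, lv)))^2)
  f_freq <- (ss_f / 1) / (ss_res / (12 - 4))
  f_int <- (ss_int / 1) / (ss_res / (12 - 4))
  expect_equal(out$p_freq, stats::pf(f_freq, 1, 8, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(out$p_interaction, stats::pf(f_int, 1, 8, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs are flagged, not thrown", {
  # zero total variance: not sensitive, p undefined
  flat <- array(1, dim = c(3, 2, 4))
  out <- frequencySensitivity(flat)
  expect_false(out$is_sensitive)
  expect_true(out$degenerate)
  expect_true(is.na(out$p_freq))
  # deterministic frequency effect with zero within-cell variance:
  # infinite-F convention makes the neuron sensitive
  det <- tensorFromMeans(matrix(c(1, 2, 3, 1, 2, 3), 3, 2), n_trial = 4)
  out2 <- frequencySensitivity(det)
  expect_true(out2$is_sensitive)
  expect_true(out2$degenerate)
  expect_equal(out2$p_freq, 0)
})

test_that("FRA construction is the exact per-cell trial mean", {
  g <- tinyGrid()
  tens <- tensorFromMeans(matrix(runif(10), 5, 2), 4, noise_sd = 1, seed = 2)
  tens <- abs(tens)
  fra <- buildFRA(tens)
  oracle <- apply(tens, c(1, 2), mean)
  expect_equal(fra, oracle, tolerance = 1e-12)
  # identical trials: FRA equals any single trial
  same <- tensorFromMeans(matrix(1:10, 5, 2), 4)
  expect_equal(buildFRA(same), matrix(1:10, 5, 2))
  expect_equal(buildFRA(array(c(0, 2), c(1, 1, 2)))[1, 1], 1)
  expect_error(buildFRA(matrix(1, 2, 2)), "array")
})

test_that("display smoothing is normalized and matches direct convolution", {
  m <- matrix(5, 6, 4)
  expect_equal(smoothFRA(m), m)
  # mass conservation for a central impulse
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  expect_equal(sum(smoothFRA(imp)), 1, tolerance = 1e-12)
  # direct double-loop convolution oracle with edge replication
  set.seed(8)
  x <- matrix(rnorm(30), 6, 5)
  k1 <- exp(-c(1, 0, 1) / 2); k1 <- k1 / sum(k1)
  oracle <- matrix(0, 6, 5)
  for (i in 1:6) for (j in 1:5) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), 6); jj <- min(max(j + dj, 1), 5)
      acc <- acc + k1[di + 2] * k1[dj + 2] * x[ii, jj]
    }
    oracle[i, j] <- acc
  }
  expect_equal(smoothFRA(x), oracle, tolerance = 1e-12)
  expect_warning(smoothFRA(matrix(1, 2, 2)), "kernel")
})

test_that("best frequency is the argmax with low-frequency tie-break", {
  expect_equal(bestFrequency(c(0, 1, 0), c(1000, 2000, 4000)), 2000)
  bf <- bestFrequency(c(1, 1), c(4000, 8000))
  expect_equal(as.numeric(bf), 4000)
  flat <- bestFrequency(c(2, 2, 2), c(1, 2, 4) * 1000)
  expect_true(isTRUE(attr(flat, "degenerate")))
  # linear-scan argmax oracle on random profiles
  set.seed(11)
  f <- 1000 * 2^(0:9 / 4)
  for (k in 1:200) {
    p <- runif(10)
    expect_equal(bestFrequency(p, f), f[which(p == max(p))[1]])
  }
})

test_that("bandwidth is the contiguous half-maximum span around BF", {
  f <- 1000 * 2^(0.25 * (0:4))
  expect_equal(bandwidthOct(c(0, 0.6, 1.0, 0.6, 0), f[3], f), 0.5)
  expect_equal(bandwidthOct(c(0, 1, 0), 2000, c(1000, 2000, 4000)), 0)
  expect_true(is.na(bandwidthOct(c(0, 0, 0), 1000, c(1000, 2000, 4000))))
  # analytic FWHM of a log2-Gaussian bump on a fine grid (one grid step
  # of slack each side)
  ff <- 1000 * 2^seq(0, 4, by = 0.05)
  for (w in c(0.43, 0.81, 1.27)) {
    prof <- exp(-4 * log(2) * (log2(ff / 4000))^2 / w^2)
    expect_lt(abs(bandwidthOct(prof, 4000, ff) - w), 0.101)
  }
})

test_that("the 75% run classifier labels forced examples correctly", {
  f5 <- 1000 * 2^(0:4)
  expect_equal(classifyFRA(c(0, 0, 1, 0, 0), f5)$label, "single")
  r <- classifyFRA(c(1.0, 0.2, 0.9), c(1000, 2000, 4000))
  expect_equal(r$label, "double")
  expect_equal(r$bf_hz, 1000)
  expect_equal(r$peak2_hz, 4000)
  expect_equal(classifyFRA(c(1.0, 0.1, 0.9, 0.1, 0.8), f5)$label, "complex")
  # threshold is strict: a bridge exactly at 0.75*max does not join runs
  expect_equal(classifyFRA(c(1, 0.75, 1, 0.2, 0.2), f5)$n_runs, 2L)
  expect_true(is.na(classifyFRA(c(0, 0, 0), c(1, 2, 4))$label))
})

test_that("run counting equals a connected-component oracle on random profiles", {
  set.seed(23)
  f <- 1000 * 2^(0:19 / 4)
  for (k in 1:2000) {
    p <- pmax(0, runif(20) - 0.3)
    if (max(p) <= 0) next
    res <- classifyFRA(p, f)
    expect_identical(res$n_runs, regionCount(p, 0.75 * max(p)))
    # BF lies in the suprathreshold run containing the global max,
    # and the bandwidth interval contains BF by construction
    expect_true(p[match(res$bf_hz, f)] == max(p))
    if (res$label == "double") expect_true(res$peak2_hz != res$bf_hz)
  }
})

test_that("Fano factor is variance over mean with scale covariance", {
  g <- c(1000, 2000); lv <- c(50, 70)
  mk <- function(trials) {
    arr <- array(0, c(2, 2, length(trials)),
                 dimnames = list(g, lv, NULL))
    arr[1, 2, ] <- trials
    arr
  }
  expect_equal(fanoFactor(mk(c(2, 2, 2, 2)), 1000, 70), 0)
  expect_equal(fanoFactor(mk(c(0, 2)), 1000, 70), 2)
  expect_true(is.na(fanoFactor(mk(c(0, 0)), 1000, 70)))
  # scale covariance: FF(k * x) = k * FF(x)
  set.seed(31)
  x <- rpois(40, 5)
  for (k in c(0.5, 2, 7))
    expect_equal(fanoFactor(mk(k * x), 1000, 70),
                 k * fanoFactor(mk(x), 1000, 70), tolerance = 1e-12)
  # best level defaults to the level with the largest mean at BF
  expect_equal(fanoFactor(mk(c(0, 2)), 1000), 2)
})

test_that("neuropil correction inverts the additive contamination", {
  own <- matrix(runif(20, 1, 2), 4)
  npil <- matrix(runif(20), 4)
  expect_equal(neuropilCorrect(own, npil, r = 0), own)
  mixed <- own + 0.7 * npil
  expect_equal(neuropilCorrect(mixed, npil, r = 0.7), own, tolerance = 1e-12)
  # rectification at zero
  expect_true(all(neuropilCorrect(matrix(0, 4, 5), npil, 0.7) == 0))
  expect_error(neuropilCorrect(own, npil[, 1:3]), "shape")
  expect_error(neuropilCorrect(own, npil, r = 1.2), "0, 1")
})
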