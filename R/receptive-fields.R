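#' Evoked activity from an event-rate trace
#'
#' Mean of the inferred event-rate trace over a response window starting at
#' stimulus onset and lasting twice the stimulus duration (closed-open in
#' samples).
#'
#' @param trace numeric time series of inferred event rate.
#' @param onset stimulus onset time (same units as \code{1/fs}).
#' @param stim_duration stimulus duration.
#' @param fs sampling rate of the trace (samples per time unit).
#' @return scalar mean over the window.
#' @export
evokedActivity <- function(trace, onset, stim_duration, fs = 1) {
  i0 <- floor(onset * fs) + 1L
  n_win <- max(1L, round(2 * stim_duration * fs))
  i1 <- i0 + n_win - 1L
  if (i0 < 1L || i1 > length(trace))
    stop("response window [", i0, ", ", i1, "] exceeds the trace extent")
  mean(trace[i0:i1])
}

#' Two-way ANOVA test for frequency sensitivity
#'
#' Balanced fixed-effects two-way ANOVA of the evoked responses with tone
#' frequency and sound level as categorical predictors, including their
#' interaction. A neuron is called frequency-sensitive when the main effect
#' of frequency or the frequency/level interaction is significant at
#' \code{alpha}.
#'
#' Degenerate inputs are flagged rather than thrown: with zero total
#' variance the neuron is not sensitive and all p-values are NA; with zero
#' within-cell (residual) variance but structure across cells the F
#' statistics are infinite and the corresponding p-values are reported as 0
#' (the infinite-F convention), so noiseless responses that genuinely
#' depend on frequency are called sensitive.
#'
#' @param responses numeric array \code{[n_freq x n_level x n_trial]} of
#'   evoked responses.
#' @param alpha significance level (default 0.05).
#' @return list with \code{p_freq}, \code{p_level}, \code{p_interaction},
#'   \code{is_sensitive} and \code{degenerate}.
#' @export
frequencySensitivity <- function(responses, alpha = 0.05) {
  stopifnot(length(dim(responses)) == 3L, dim(responses)[3] >= 2L)
  d <- dim(responses)
  if (stats::var(as.vector(responses)) == 0 ||
      !is.finite(stats::var(as.vector(responses))))
    return(list(p_freq = NA_real_, p_level = NA_real_,
                p_interaction = NA_real_, is_sensitive = FALSE,
                degenerate = TRUE))
  df <- data.frame(
    response = as.vector(responses),
    freq = factor(rep(rep(seq_len(d[1]), d[2]), d[3])),
    level = factor(rep(rep(seq_len(d[2]), each = d[1]), d[3])))
  one_level <- d[2] == 1L
  fit <- if (one_level) stats::aov(response ~ freq, data = df)
  else stats::aov(response ~ freq * level, data = df)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  n_eff <- length(ss) - 1L
  p <- tab[["Pr(>F)"]][seq_len(n_eff)]
  degenerate <- FALSE
  if (ss[n_eff + 1L] <= 1e-12 * sum(ss)) {
    ## no within-cell variance: infinite F for any effect with signal
    degenerate <- TRUE
    p <- ifelse(ss[seq_len(n_eff)] > 1e-12 * sum(ss), 0, 1)
  }
  if (one_level) p <- c(p[1], NA_real_, NA_real_)
  list(p_freq = p[1], p_level = p[2], p_interaction = p[3],
       is_sensitive = isTRUE(p[1] < alpha) || isTRUE(p[3] < alpha),
       degenerate = degenerate)
}

#' Frequency response area (trial-averaged responses)
#'
#' @param responses numeric array \code{[n_freq x n_level x n_trial]}.
#' @return matrix \code{[n_freq x n_level]} of per-cell trial means,
#'   keeping the frequency/level dimnames.
#' @export
buildFRA <- function(responses) {
  if (is.null(dim(responses)) || length(dim(responses)) != 3L ||
      any(dim(responses) == 0L))
    stop("responses must be a nonempty [n_freq x n_level x n_trial] array")
  d <- dim(responses)
  out <- matrix(rowMeans(matrix(responses, d[1] * d[2], d[3])), d[1], d[2])
  dimnames(out) <- dimnames(responses)[1:2]
  out
}

#' Smooth an FRA for display
#'
#' Separable 3-point Gaussian convolution (kernel 1-2-1 scaled by the
#' Gaussian weights at -1, 0, 1 SD) with edge replication. Intended for
#' plotting only; classification always runs on the raw profile.
#'
#' @param fra matrix \code{[n_freq x n_level]}.
#' @return smoothed matrix of the same shape.
#' @export
smoothFRA <- function(fra) {
  if (nrow(fra) < 3L || ncol(fra) < 3L)
    warning("matrix smaller than the 3x3 kernel; edges dominate the result")
  k <- exp(-c(1, 0, 1) / 2)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(v[1], v, v[length(v)])
    k[1] * vp[seq_along(v)] + k[2] * vp[seq_along(v) + 1L] +
      k[3] * vp[seq_along(v) + 2L]
  }
  out <- apply(fra, 2, pad_conv)
  out <- t(apply(out, 1, pad_conv))
  dimnames(out) <- dimnames(fra)
  out
}

#' Level-averaged tuning profile
#'
#' @param fra matrix \code{[n_freq x n_level]} from [buildFRA()].
#' @return named numeric vector over frequencies (names = Hz).
#' @export
tuningProfile <- function(fra) rowMeans(fra)

#' Best frequency of a tuning profile
#'
#' The frequency eliciting the highest level-averaged response. Ties are
#' broken toward the lowest frequency so the result does not depend on
#' storage order.
#'
#' @param profile numeric tuning profile.
#' @param frequencies_hz frequencies of the profile entries; defaults to
#'   \code{as.numeric(names(profile))}.
#' @return best frequency in Hz; attribute \code{degenerate} is TRUE for an
#'   all-equal profile.
#' @export
bestFrequency <- function(profile, frequencies_hz = as.numeric(names(profile))) {
  stopifnot(length(profile) >= 1L, length(profile) == length(frequencies_hz))
  bf <- frequencies_hz[which.max(profile)]
  if (length(unique(profile)) == 1L) attr(bf, "degenerate") <- TRUE
  bf
}

#' Tuning bandwidth in octaves
#'
#' The continuous range of frequencies around BF whose level-averaged
#' response exceeds 50\% of the response at BF, expressed as
#' \code{log2(f_right / f_left)}. A peak confined to a single grid
#' frequency has bandwidth 0.
#'
#' @inheritParams bestFrequency
#' @param bf_hz the best frequency (must be one of the grid frequencies).
#' @return bandwidth in octaves, or NA (flagged) when the response at BF is
#'   not positive.
#' @export
bandwidthOct <- function(profile, bf_hz,
                         frequencies_hz = as.numeric(names(profile))) {
  i_bf <- match(bf_hz, frequencies_hz)
  if (is.na(i_bf)) stop("bf_hz is not one of the profile frequencies")
  p_bf <- profile[i_bf]
  if (p_bf <= 0) return(NA_real_)
  thr <- 0.5 * p_bf
  lo <- i_bf
  while (lo > 1L && profile[lo - 1L] > thr) lo <- lo - 1L
  hi <- i_bf
  while (hi < length(profile) && profile[hi + 1L] > thr) hi <- hi + 1L
  log2(frequencies_hz[hi] / frequencies_hz[lo])
}

#' Classify a tuning profile as single-, double-peaked or complex
#'
#' Thresholds the level-averaged profile at 75\% of its maximum and counts
#' maximal runs of consecutive grid frequencies strictly above threshold:
#' one run is single-peaked, two runs double-peaked, three or more complex.
#' BF is the global argmax (ties toward the lowest frequency). For
#' double-peaked profiles, peak 2 is the argmax of the run not containing
#' BF.
#'
#' @inheritParams bestFrequency
#' @return list with \code{label}, \code{bf_hz}, \code{peak2_hz} (NA unless
#'   double), and \code{n_runs}; all NA with \code{label = NA} when the
#'   profile maximum is not positive (flagged degenerate).
#' @examples
#' classifyFRA(c(1, 0.2, 0.9), c(1000, 2000, 4000))
#' @export
classifyFRA <- function(profile, frequencies_hz = as.numeric(names(profile))) {
  stopifnot(length(profile) == length(frequencies_hz))
  m <- max(profile)
  if (!is.finite(m) || m <= 0)
    return(list(label = NA_character_, bf_hz = NA_real_, peak2_hz = NA_real_,
                n_runs = 0L, degenerate = TRUE))
  above <- profile > 0.75 * m
  r <- rle(above)
  n_runs <- sum(r$values)
  i_bf <- which.max(profile)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  peak2 <- NA_real_
  if (n_runs == 2L) {
    other <- which(above & run_id != run_id[i_bf])
    peak2 <- frequencies_hz[other[which.max(profile[other])]]
  }
  list(label = c("single", "double", "complex")[min(n_runs, 3L)],
       bf_hz = frequencies_hz[i_bf], peak2_hz = peak2, n_runs = n_runs)
}

#' Fano factor at the best frequency/level combination
#'
#' Across-trial variance of the evoked response at the neuron's best
#' frequency and best level, divided by the across-trial mean. Uses the
#' unbiased (n - 1) variance estimator.
#'
#' @param responses array \code{[n_freq x n_level x n_trial]}.
#' @param bf_hz best frequency (a grid frequency).
#' @param best_level_db level of the best cell; if NULL, the level with the
#'   largest trial-averaged response at BF.
#' @param frequencies_hz,levels_db the grid axes; default from dimnames.
#' @return Fano factor, or NA (flagged) when the trial mean is 0.
#' @export
fanoFactor <- function(responses, bf_hz, best_level_db = NULL,
                       frequencies_hz = as.numeric(dimnames(responses)[[1]]),
                       levels_db = as.numeric(dimnames(responses)[[2]])) {
  i <- match(bf_hz, frequencies_hz)
  if (is.na(i)) stop("bf_hz is not one of the grid frequencies")
  if (is.null(best_level_db)) {
    j <- which.max(apply(responses[i, , , drop = FALSE], 2, mean))
  } else {
    j <- match(best_level_db, levels_db)
    if (is.na(j)) stop("best_level_db is not one of the grid levels")
  }
  x <- responses[i, j, ]
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::var(x) / m
}

#' Subtract the neuropil signal from contaminated responses
#'
#' \code{corrected = mixed - r * neuropil}, rectified at zero. The standard
#' first-order correction for contamination of a somatic signal by the
#' surrounding neuropil.
#'
#' @param responses_mixed numeric array/matrix of contaminated responses.
#' @param neuropil_responses neuropil signal of the same shape (or a vector
#'   recycled along the first dimension of a matrix input).
#' @param r correction coefficient in [0, 1] (default 0.7).
#' @return corrected responses, same shape as \code{responses_mixed}.
#' @export
neuropilCorrect <- function(responses_mixed, neuropil_responses, r = 0.7) {
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (!identical(dim(responses_mixed), dim(neuropil_responses)) &&
      !(is.matrix(responses_mixed) &&
        length(neuropil_responses) == ncol(responses_mixed)))
    stop("responses_mixed and neuropil_responses shapes do not match")
  if (is.matrix(responses_mixed) && is.null(dim(neuropil_responses)))
    neuropil_responses <- matrix(neuropil_responses,
                                 nrow(responses_mixed),
                                 ncol(responses_mixed), byrow = TRUE)
  out <- responses_mixed - r * neuropil_responses
  out[out < 0] <- 0
  out
}

#' Per-neuron receptive-field analysis of a whole field
#'
#' Runs the full single-neuron pipeline over every neuron of a field:
#' frequency-sensitivity ANOVA, FRA and tuning profile, 75\%-threshold
#' shape classification, best frequency, bandwidth, Fano factor and the
#' trial-mean response at the best frequency/level combination.
#'
#' @param field an [ImagingField-class].
#' @param alpha significance level for the sensitivity test.
#' @param neuropil_r if non-NULL and the field carries a stored neuropil
#'   signal, responses are neuropil-corrected with this coefficient before
#'   analysis.
#' @return data.frame with one row per neuron: neuron_id, x_um, y_um,
#'   axis_mm, is_sensitive, p_freq, p_level, p_interaction, label, bf_hz,
#'   peak2_hz, bandwidth_oct, fano_factor, response_at_bf, degenerate.
#' @export
classifyNeurons <- function(field, alpha = 0.05, neuropil_r = NULL) {
  grid <- stimulusGrid(field)
  pos <- neuronPositions(field)
  npil <- metadata(field)$neuropil
  resp <- assay(field, "responses")
  if (!is.null(neuropil_r) && !is.null(npil))
    resp <- neuropilCorrect(resp, npil, r = neuropil_r)
  n <- nrow(resp)
  out <- data.frame(
    neuron_id = pos$neuron_id, x_um = pos$x_um, y_um = pos$y_um,
    axis_mm = pos$axis_mm,
    is_sensitive = FALSE, p_freq = NA_real_, p_level = NA_real_,
    p_interaction = NA_real_, label = NA_character_, bf_hz = NA_real_,
    peak2_hz = NA_real_, bandwidth_oct = NA_real_, fano_factor = NA_real_,
    response_at_bf = NA_real_, degenerate = FALSE)
  nf <- length(grid@frequencies_hz)
  nl <- length(grid@levels_db)
  for (i in seq_len(n)) {
    tens <- array(resp[i, ], dim = c(nf, nl, grid@n_trials),
                  dimnames = list(as.character(grid@frequencies_hz),
                                  as.character(grid@levels_db), NULL))
    sens <- frequencySensitivity(tens, alpha = alpha)
    out$is_sensitive[i] <- sens$is_sensitive
    out$p_freq[i] <- sens$p_freq
    out$p_level[i] <- sens$p_level
    out$p_interaction[i] <- sens$p_interaction
    out$degenerate[i] <- sens$degenerate
    if (!sens$is_sensitive) next
    fra <- buildFRA(tens)
    prof <- tuningProfile(fra)
    cls <- classifyFRA(prof, grid@frequencies_hz)
    out$label[i] <- cls$label
    out$bf_hz[i] <- cls$bf_hz
    out$peak2_hz[i] <- cls$peak2_hz
    if (is.na(cls$label)) { out$degenerate[i] <- TRUE; next }
    out$bandwidth_oct[i] <- bandwidthOct(prof, cls$bf_hz,
                                         grid@frequencies_hz)
    i_bf <- match(cls$bf_hz, grid@frequencies_hz)
    j_best <- which.max(fra[i_bf, ])
    out$response_at_bf[i] <- fra[i_bf, j_best]
    out$fano_factor[i] <- fanoFactor(tens, cls$bf_hz, grid@levels_db[j_best],
                                     frequencies_hz = grid@frequencies_hz,
                                     levels_db = grid@levels_db)
  }
  out
}
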