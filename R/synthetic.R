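#' Generative FRA template
#'
#' Builds the noiseless frequency response area of one model neuron on a
#' stimulus grid. Each frequency peak is a Gaussian bump in log2-frequency
#' whose full width at half maximum equals \code{bandwidth_oct} at the
#' lowest sound level and widens linearly with level (producing the V-shape
#' characteristic of A1 FRAs); response amplitude also grows with level, so
#' the matrix maximum sits at (BF, highest level).
#'
#' Shape classes: \code{"single"} has one bump at \code{bf_hz};
#' \code{"double"} adds a second bump at \code{peak2_hz} scaled by
#' \code{peak2_gain_ratio} (< 1, so the BF peak dominates); \code{"complex"}
#' has at least three bumps, the largest at \code{bf_hz}, the others given
#' by \code{extra_peaks}; \code{"nonsensitive"} is flat zero.
#'
#' @param class one of \code{"single"}, \code{"double"}, \code{"complex"},
#'   \code{"nonsensitive"}.
#' @param bf_hz best frequency (Hz); must lie within the grid range.
#' @param bandwidth_oct FWHM of each peak, in octaves, at the lowest level.
#' @param grid a [StimulusGrid-class].
#' @param peak2_hz second peak frequency (double class only).
#' @param peak2_gain_ratio amplitude of peak 2 relative to the BF peak
#'   (must be < 1).
#' @param extra_peaks data.frame with columns \code{freq_hz}, \code{gain}
#'   (each gain < 1) giving the secondary bumps of a complex neuron; if
#'   omitted, two bumps 1.5 octaves either side of BF with gains 0.85/0.8.
#' @param widen_per_db fractional bandwidth increase per dB above the lowest
#'   level (default 0.01, i.e. +60 dB widens the peak by 60\%).
#' @param amp_range amplitude multipliers at the lowest and highest level.
#' @return numeric matrix \code{[n_freq x n_level]}, peak value 1 before any
#'   gain scaling, all entries >= 0.
#' @examples
#' tpl <- fraTemplate("single", 8000, 0.5, ferretGrid())
#' which.max(rowMeans(tpl))
#' @export
fraTemplate <- function(class, bf_hz, bandwidth_oct, grid,
                        peak2_hz = NULL, peak2_gain_ratio = 0.85,
                        extra_peaks = NULL,
                        widen_per_db = 0.01, amp_range = c(0.6, 1)) {
  class <- match.arg(class, c("single", "double", "complex", "nonsensitive"))
  f <- grid@frequencies_hz
  lv <- grid@levels_db
  out <- matrix(0, length(f), length(lv),
                dimnames = list(as.character(f), as.character(lv)))
  if (class == "nonsensitive") {
    if (!is.null(peak2_hz))
      stop("peak2_hz is only meaningful for the double class")
    return(out)
  }
  if (bf_hz < min(f) || bf_hz > max(f))
    stop("bf_hz must lie within the grid frequency range")
  if (class != "double" && !is.null(peak2_hz))
    stop("peak2_hz is only meaningful for the double class")
  if (class == "double") {
    if (is.null(peak2_hz))
      stop("double class requires peak2_hz")
    if (peak2_gain_ratio >= 1 || peak2_gain_ratio <= 0)
      stop("peak2_gain_ratio must lie in (0, 1)")
  }
  peaks <- data.frame(freq_hz = bf_hz, gain = 1)
  if (class == "double")
    peaks <- rbind(peaks, data.frame(freq_hz = peak2_hz,
                                     gain = peak2_gain_ratio))
  if (class == "complex") {
    if (is.null(extra_peaks))
      extra_peaks <- data.frame(
        freq_hz = pmin(pmax(bf_hz * 2^c(-1.5, 1.5), min(f)), max(f)),
        gain = c(0.85, 0.8))
    if (nrow(extra_peaks) < 2L)
      stop("complex class requires >= 2 extra peaks (>= 3 bumps in total)")
    if (any(extra_peaks$gain >= 1))
      stop("extra peak gains must be < 1 so the largest bump stays at BF")
    peaks <- rbind(peaks, extra_peaks[, c("freq_hz", "gain")])
  }
  lf <- log2(f)
  amp <- if (length(lv) == 1L) amp_range[2] else
    amp_range[1] + diff(amp_range) * (seq_along(lv) - 1) / (length(lv) - 1)
  for (j in seq_along(lv)) {
    fwhm <- bandwidth_oct * (1 + widen_per_db * (lv[j] - lv[1]))
    prof <- rep(0, length(f))
    for (k in seq_len(nrow(peaks)))
      prof <- prof + peaks$gain[k] *
        exp(-4 * log(2) * (lf - log2(peaks$freq_hz[k]))^2 / fwhm^2)
    out[, j] <- amp[j] * prof
  }
  out
}

## default noise model: magnitudes chosen so that trial-averaged profiles
## are clean relative to unit peak gains, while same-class noise
## correlations land near the values typical of A1 population imaging
## (~0.14 for simple cells, ~0.05 for complex; see the methods vignette).
defaultNoise <- function() {
  list(family = "gaussian",
       sd_independent = 0.15,
       sd_shared = 0.1,
       loading = c(single = 0.6, double = 0.6, complex = 0.35,
                   nonsensitive = 0.45),
       baseline = 0)
}

## ferret-wide class mixture: 19.23% frequency-sensitive neurons split
## 42.71 / 31.75 / 24.96 across single / double / complex
defaultClassMix <- function() {
  sens <- 0.1923
  p <- sens * c(single = 0.4271, double = 0.3175, complex = 0.2496)
  c(p, nonsensitive = 1 - sum(p))
}

#' Generate a synthetic imaging field with known ground truth
#'
#' Emulates one two-photon imaging field of A1 layer 2/3: neurons are placed
#' uniformly in the rectangle; each neuron's true best frequency is the
#' species tonotopic-gradient frequency at its projected axis coordinate,
#' jittered by a zero-mean log2-normal with a class-dependent SD
#' (\code{bf_scatter_oct}); trial responses are the neuron's FRA template
#' plus a field-common trial fluctuation (weighted by the neuron's
#' shared-noise loading) plus independent noise, rectified at zero. An
#' optional neuropil mixing step replaces each stored response by
#' \code{(1 - c) * own + c * field-average}, emulating contamination of the
#' somatic signal by surrounding neuropil.
#'
#' Double-peaked neurons get a second, weaker peak at a frequency drawn
#' uniformly (in octaves) within the grid, deliberately unrelated to the
#' tonotopic gradient; complex neurons get two further such bumps.
#'
#' @param species a [SpeciesParams-class] or preset name.
#' @param grid a [StimulusGrid-class]; default matches the species preset.
#' @param n_neurons number of neurons (>= 1).
#' @param class_mix named proportions over single/double/complex/
#'   nonsensitive, summing to 1. Default: the ferret-wide mixture with
#'   19.23\% sensitive neurons split 42.71/31.75/24.96.
#' @param bf_scatter_oct named per-class SD (octaves) of BF jitter around
#'   the gradient. Default 0.3/0.7/1.2 for single/double/complex.
#' @param noise list with \code{family} ("gaussian" or "poisson"),
#'   \code{sd_independent}, \code{sd_shared}, per-class \code{loading} on
#'   the shared fluctuation, and \code{baseline} (a flat response offset
#'   added to every template; raise it to keep rectification from
#'   truncating the noise). The Poisson family draws each trial response as
#'   Poisson with the template value as mean (for Fano-factor work).
#' @param neuropil_coeff mixing weight c in [0, 1); 0 leaves responses
#'   untouched.
#' @param seed integer master seed; per-neuron substreams are derived from
#'   it, so fields are reproducible neuron-by-neuron.
#' @param width_um,height_um field extent (default 250 x 250 um).
#' @param axis_position_mm field centre on the tonotopic axis (default
#'   mid-axis).
#' @param axis_angle tonotopic axis direction in field coordinates (rad).
#' @param field_id field identifier.
#' @param peak2_gain_ratio_range range of the relative gain of secondary
#'   peaks (drawn uniformly; must stay above the 0.75 classifier threshold
#'   with enough margin that sampling a bump off the frequency grid does
#'   not suppress it, and below 1 so the BF peak dominates).
#' @param bandwidth_mean_oct,bandwidth_sd_oct FWHM distribution of the
#'   single-peaked class (defaults 0.74/0.1, truncated at 0.3); multi-peaked
#'   classes use mean 0.8.
#' @return An [ImagingField-class] with ground truth in \code{rowData} and,
#'   when \code{neuropil_coeff > 0}, the common neuropil signal in
#'   \code{metadata()$neuropil}.
#' @examples
#' fld <- generateField("ferret", n_neurons = 20, seed = 1)
#' fld
#' @export
generateField <- function(species = "ferret",
                          grid = NULL,
                          n_neurons = 60,
                          class_mix = defaultClassMix(),
                          bf_scatter_oct = c(single = 0.3, double = 0.7,
                                             complex = 1.2),
                          noise = defaultNoise(),
                          neuropil_coeff = 0,
                          seed = 1,
                          width_um = 250, height_um = 250,
                          axis_position_mm = NULL,
                          axis_angle = 0,
                          field_id = "field1",
                          peak2_gain_ratio_range = c(0.84, 0.895),
                          bandwidth_mean_oct = 0.74,
                          bandwidth_sd_oct = 0.1) {
  if (is.character(species)) species <- speciesPreset(species)
  if (is.null(grid))
    grid <- if (species@name == "mouse") mouseGrid() else ferretGrid()
  if (n_neurons < 1L) stop("n_neurons must be >= 1")
  classes <- c("single", "double", "complex", "nonsensitive")
  if (is.null(names(class_mix))) names(class_mix) <- classes
  class_mix <- class_mix[classes]
  if (anyNA(class_mix) || abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must give proportions for the four classes summing to 1")
  noise <- utils::modifyList(defaultNoise(), noise)
  if (is.null(axis_position_mm))
    axis_position_mm <- species@axis_length_mm / 2
  if (neuropil_coeff < 0 || neuropil_coeff >= 1)
    stop("neuropil_coeff must lie in [0, 1)")

  withSeed(seed, {
    f <- grid@frequencies_hz
    lgr <- range(log2(f))
    n_col <- length(f) * length(grid@levels_db) * grid@n_trials
    x_um <- stats::runif(n_neurons, 0, width_um)
    y_um <- stats::runif(n_neurons, 0, height_um)
    lbl <- sample(classes, n_neurons, replace = TRUE, prob = class_mix)
    ## field-common trial fluctuation, one value per presentation
    shared <- stats::rnorm(n_col, 0, noise$sd_shared)
    neuron_seed <- sample.int(.Machine$integer.max, n_neurons)

    slope <- tonotopicSlope(species)
    proj_um <- (x_um - width_um / 2) * cos(axis_angle) +
      (y_um - height_um / 2) * sin(axis_angle)
    axis_mm <- axis_position_mm + proj_um / 1000
    ## gradient runs low->high frequency across the species axis
    grad_l2 <- log2(species@hearing_lo_hz) + slope * axis_mm

    own <- matrix(0, n_neurons, n_col)
    gt <- data.frame(true_class = lbl, true_bf_hz = NA_real_,
                     true_peak2_hz = NA_real_, true_bandwidth_oct = NA_real_,
                     peak_gain = NA_real_,
                     shared_noise_loading = noise$loading[lbl],
                     neuropil_coeff = neuropil_coeff)
    for (i in seq_len(n_neurons)) {
      set.seed(neuron_seed[i])
      cls <- lbl[i]
      if (cls == "nonsensitive") {
        tpl <- matrix(0, length(f), length(grid@levels_db))
        gain <- 0
      } else {
        sc <- bf_scatter_oct[[cls]]
        ## peak frequencies are snapped to the probed grid: the stimulus
        ## grid sets the resolution at which a peak is identifiable, so
        ## on-grid ground truth is exactly recoverable in the noiseless
        ## limit
        lf_grid <- log2(f)
        ## snap returns the log2 grid value, hz the exact grid frequency
        ## (re-exponentiating log2 values can drift off the grid by 1 ulp)
        snap <- function(l2) lf_grid[which.min(abs(lf_grid - l2))]
        hz <- function(l2) f[which.min(abs(lf_grid - l2))]
        bf_l2 <- snap(clamp(grad_l2[i] + stats::rnorm(1, 0, sc),
                            lgr[1], lgr[2]))
        bf <- hz(bf_l2)
        ## multi-peaked bandwidths are floored at 0.6 oct so that sampling
        ## the main bump off the frequency grid can never attenuate it
        ## below the strongest allowed secondary peak
        ## multi-peaked bandwidths are kept in [0.4, 0.9] oct, and peaks
        ## at least 1.7 bandwidths apart, so the dip between two bumps
        ## always falls below the 75% classifier threshold
        bw_mean <- if (cls == "single") bandwidth_mean_oct else 0.8
        bw <- if (cls == "single")
          max(0.3, stats::rnorm(1, bw_mean, bandwidth_sd_oct))
        else clamp(stats::rnorm(1, bw_mean, bandwidth_sd_oct), 0.4, 0.9)
        gain <- exp(stats::rnorm(1, log(switch(cls, single = 1,
                                               double = 0.8,
                                               complex = 0.7)), 0.2))
        peak2 <- NULL
        extra <- NULL
        ## peaks at least 1.7 bandwidths apart keep the inter-peak dip
        ## below the 75% classifier threshold
        min_sep <- 1.7 * bw
        if (cls == "double") {
          ## peak 2 is drawn first, uniform over the grid and independent
          ## of the neuron's position: conditioning anything on peak 2
          ## (never the reverse) keeps peak 2 free of tonotopic structure,
          ## the property the recorded data show for second peaks. A
          ## conflict with the BF is resolved by narrowing the neuron's
          ## bumps; only near-coincident draws displace the BF jitter.
          p2_l2 <- snap(stats::runif(1, lgr[1], lgr[2]))
          sep_floor <- 1.7 * 0.4
          if (abs(bf_l2 - p2_l2) < sep_floor) {
            for (try in seq_len(100L)) {
              bf_l2 <- snap(clamp(grad_l2[i] + stats::rnorm(1, 0, sc),
                                  lgr[1], lgr[2]))
              if (abs(bf_l2 - p2_l2) >= sep_floor) break
            }
            if (abs(bf_l2 - p2_l2) < sep_floor) {
              ok <- lf_grid[abs(lf_grid - p2_l2) >= sep_floor]
              bf_l2 <- ok[which.min(abs(ok - grad_l2[i]))]
            }
          }
          bw <- min(bw, abs(bf_l2 - p2_l2) / 1.7)
          bf <- hz(bf_l2)
          peak2 <- hz(p2_l2)
          gt$true_peak2_hz[i] <- peak2
        } else if (cls == "complex") {
          ## + 0.3 oct margin: snapping to the grid can move each peak by
          ## up to half a grid step
          pp <- drawPeakPair(bf_l2, lgr, min_sep = min_sep + 0.3)
          p1 <- pp[1]
          p2 <- pp[2]
          extra <- data.frame(freq_hz = c(hz(p1), hz(p2)),
                              gain = stats::runif(2, peak2_gain_ratio_range[1],
                                                  peak2_gain_ratio_range[2]))
        }
        ratio <- stats::runif(1, peak2_gain_ratio_range[1],
                              peak2_gain_ratio_range[2])
        tpl <- fraTemplate(cls, bf, bw, grid, peak2_hz = peak2,
                           peak2_gain_ratio = ratio, extra_peaks = extra)
        gt$true_bf_hz[i] <- bf
        gt$true_bandwidth_oct[i] <- bw
      }
      gt$peak_gain[i] <- gain
      mu <- rep(as.vector(gain * tpl), grid@n_trials) + noise$baseline
      own[i, ] <- if (noise$family == "poisson") {
        stats::rpois(n_col, mu)
      } else {
        pmax(0, mu + noise$loading[[cls]] * shared +
               stats::rnorm(n_col, 0, noise$sd_independent))
      }
    }
    npil <- colMeans(own)
    stored <- if (neuropil_coeff > 0) {
      (1 - neuropil_coeff) * own +
        neuropil_coeff * matrix(npil, n_neurons, n_col, byrow = TRUE)
    } else own
    ImagingField(stored, x_um, y_um, grid, species,
                 field_id = field_id, width_um = width_um,
                 height_um = height_um,
                 axis_position_mm = axis_position_mm,
                 axis_angle = axis_angle,
                 ground_truth = gt,
                 neuropil = if (neuropil_coeff > 0) npil else NULL)
  })
}

#' Generate a cohort of fields spread along the tonotopic axis
#'
#' Field centres are placed evenly along the stretch of the tonotopic axis
#' whose gradient frequency lies within the stimulus grid (imaging outside
#' it would record neurons whose preferred frequencies the grid cannot
#' probe), clipped by half-field margins.
#'
#' @inheritParams generateField
#' @param n_fields number of imaging fields.
#' @param ... passed on to [generateField()].
#' @return list of [ImagingField-class] objects.
#' @export
generateCohort <- function(species = "ferret", n_fields = 10,
                           n_neurons = 60, seed = 1, grid = NULL, ...) {
  if (is.character(species)) species <- speciesPreset(species)
  if (is.null(grid))
    grid <- if (species@name == "mouse") mouseGrid() else ferretGrid()
  L <- species@axis_length_mm
  slope <- tonotopicSlope(species)
  ## axis window where the gradient frequency is probed by the grid
  lo <- log2(min(grid@frequencies_hz) / species@hearing_lo_hz) / slope
  hi <- log2(max(grid@frequencies_hz) / species@hearing_lo_hz) / slope
  margin <- 0.3 / 2  # half of a 300 um field, in mm
  pos <- seq(max(margin, lo), min(L - margin, hi), length.out = n_fields)
  field_seed <- withSeed(seed, sample.int(.Machine$integer.max, n_fields))
  lapply(seq_len(n_fields), function(k) {
    generateField(species = species, grid = grid, n_neurons = n_neurons,
                  seed = field_seed[k], axis_position_mm = pos[k],
                  field_id = sprintf("field%02d", k), ...)
  })
}

#' Convolve an event-rate series with a calcium indicator kernel
#'
#' Turns a deconvolved event series back into a fluorescence-like trace by
#' convolution with a causal exponential kernel whose half-decay time
#' matches the indicator (0.7 time units for GCaMP6f, 1.25 for GCaMP6m).
#' The kernel is scaled so its sum equals \code{gain}.
#'
#' @param events numeric event-rate series (one value per sample).
#' @param indicator \code{"GCaMP6f"} or \code{"GCaMP6m"}.
#' @param dt sample spacing, in the same time units as the half-decay.
#' @param gain kernel integral (default 1).
#' @param half_decay override the indicator's half-decay constant.
#' @return numeric trace of the same length as \code{events}.
#' @examples
#' tr <- convolveCalcium(c(1, rep(0, 20)), "GCaMP6f", dt = 0.1)
#' @export
convolveCalcium <- function(events, indicator = c("GCaMP6f", "GCaMP6m"),
                            dt = 1, gain = 1, half_decay = NULL) {
  indicator <- match.arg(indicator)
  if (is.null(half_decay))
    half_decay <- c(GCaMP6f = 0.7, GCaMP6m = 1.25)[[indicator]]
  n <- length(events)
  k <- 0.5^(dt * (seq_len(n) - 1) / half_decay)
  k <- gain * k / sum(k)
  out <- stats::convolve(events, rev(k), type = "open")[seq_len(n)]
  ## exact zeros stay zeros despite FFT round-off
  out[abs(out) < 1e-12] <- 0
  out
}

## -- internal helpers ------------------------------------------------------

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## draw a log2-frequency uniformly in `rng`, at least min_sep octaves from
## every value in `avoid` (falls back to the farthest draw if the range is
## too crowded)
drawAwayFrom <- function(avoid, rng, min_sep, tries = 50L) {
  best <- NA_real_
  best_d <- -Inf
  for (t in seq_len(tries)) {
    cand <- stats::runif(1, rng[1], rng[2])
    d <- min(abs(cand - avoid))
    if (d >= min_sep) return(cand)
    if (d > best_d) { best <- cand; best_d <- d }
  }
  best
}

## draw two log2-frequencies jointly, each at least min_sep octaves from
## `center` and from each other; falls back to the range ends (always a
## valid configuration when the range spans >= 2 * min_sep) if rejection
## sampling fails
drawPeakPair <- function(center, rng, min_sep, tries = 500L) {
  for (t in seq_len(tries)) {
    cand <- stats::runif(2, rng[1], rng[2])
    if (min(abs(cand - center)) >= min_sep &&
        abs(cand[1] - cand[2]) >= min_sep)
      return(cand)
  }
  ends <- if (abs(rng[1] - center) > abs(rng[2] - center))
    c(rng[1], rng[1] + min_sep) else c(rng[2] - min_sep, rng[2])
  if (min(abs(ends - center)) < min_sep)
    ends <- rng  # last resort: the two grid extremes
  ends
}

## evaluate expr with a fixed RNG state, restoring the caller's state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
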