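#' Noise correlation between two simultaneously recorded neurons
#'
#' Each neuron's per-stimulus (frequency/level) mean is subtracted from its
#' single-trial responses, and the two residual series -- flattened over
#' all stimuli and trials -- are Pearson-correlated. With zero residual
#' variance in either neuron the correlation is defined as 0 and flagged
#' (attribute \code{degenerate}), so noiseless data do not error.
#'
#' @param resp_a,resp_b arrays \code{[n_freq x n_level x n_trial]} recorded
#'   under the same grid.
#' @return Pearson correlation of the trial fluctuations.
#' @export
noiseCorrelation <- function(resp_a, resp_b) {
  stopifnot(identical(dim(resp_a), dim(resp_b)),
            length(dim(resp_a)) == 3L)
  ra <- as.vector(resp_a - replicateCells(buildFRA(resp_a), dim(resp_a)[3]))
  rb <- as.vector(resp_b - replicateCells(buildFRA(resp_b), dim(resp_b)[3]))
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    r <- 0
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  stats::cor(ra, rb)
}

#' Signal correlation between two neurons
#'
#' Pearson correlation between the two trial-averaged FRAs (flattened over
#' frequency x level), minus the pair's noise correlation. Subtracting the
#' noise correlation removes the part of the tuning similarity that is
#' inherited from shared trial-by-trial fluctuations rather than from the
#' stimulus. Because it is a difference of two correlations the value can
#' lie in [-2, 2].
#'
#' @inheritParams noiseCorrelation
#' @return signal correlation, or NA (flagged) when either FRA is constant.
#' @export
signalCorrelation <- function(resp_a, resp_b) {
  fa <- as.vector(buildFRA(resp_a))
  fb <- as.vector(buildFRA(resp_b))
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    r <- NA_real_
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  stats::cor(fa, fb) - as.numeric(noiseCorrelation(resp_a, resp_b))
}

#' Pairwise signal and noise correlations within a field
#'
#' Computes signal and noise correlations for every unordered pair of
#' frequency-sensitive neurons recorded simultaneously in one field,
#' together with their Euclidean separation in the field plane and their
#' separation along the tonotopic axis.
#'
#' @param field an [ImagingField-class].
#' @param classifications output of [classifyNeurons()] for this field.
#' @param sensitive_only keep only pairs of frequency-sensitive neurons
#'   (default TRUE).
#' @return data.frame with id_a, id_b, label_a, label_b, signal_r, noise_r,
#'   distance_um, axis_distance_um.
#' @export
pairCorrelations <- function(field, classifications, sensitive_only = TRUE) {
  keep <- if (sensitive_only)
    which(classifications$is_sensitive & !is.na(classifications$label))
  else seq_len(nrow(classifications))
  empty <- data.frame(id_a = character(), id_b = character(),
                      label_a = character(), label_b = character(),
                      signal_r = numeric(), noise_r = numeric(),
                      distance_um = numeric(), axis_distance_um = numeric())
  if (length(keep) < 2L) return(empty)
  grid <- stimulusGrid(field)
  md <- metadata(field)
  cl <- classifications[keep, , drop = FALSE]
  ## per-neuron trial-averaged FRA vectors and residual series, computed
  ## once; pairwise correlations are then plain column correlations
  n_cell <- length(grid@frequencies_hz) * length(grid@levels_db)
  resp <- t(assay(field, "responses")[keep, , drop = FALSE])
  cell <- rep(seq_len(n_cell), grid@n_trials)
  fmat <- apply(resp, 2, function(v) tapply(v, cell, mean))
  rmat <- resp - fmat[cell, , drop = FALSE]
  sd_f <- apply(fmat, 2, stats::sd)
  sd_r <- apply(rmat, 2, stats::sd)
  c_noise <- suppressWarnings(stats::cor(rmat))
  c_noise[sd_r == 0, ] <- 0
  c_noise[, sd_r == 0] <- 0
  c_sig <- suppressWarnings(stats::cor(fmat)) - c_noise
  c_sig[sd_f == 0, ] <- NA_real_
  c_sig[, sd_f == 0] <- NA_real_
  proj_um <- (cl$x_um - md$width_um / 2) * cos(md$axis_angle) +
    (cl$y_um - md$height_um / 2) * sin(md$axis_angle)
  idx <- utils::combn(length(keep), 2L)
  a <- idx[1, ]; b <- idx[2, ]
  data.frame(
    id_a = cl$neuron_id[a], id_b = cl$neuron_id[b],
    label_a = cl$label[a], label_b = cl$label[b],
    signal_r = c_sig[cbind(a, b)],
    noise_r = c_noise[cbind(a, b)],
    distance_um = sqrt((cl$x_um[a] - cl$x_um[b])^2 +
                         (cl$y_um[a] - cl$y_um[b])^2),
    axis_distance_um = abs(proj_um[a] - proj_um[b]))
}

#' Distance dependence of pairwise correlations
#'
#' Pearson correlation and linear fit of signal (or noise) correlation
#' against inter-neuron distance, either along the tonotopic axis (default)
#' or Euclidean in the field plane.
#'
#' @param pairs data.frame from [pairCorrelations()] (possibly several
#'   fields' worth, row-bound).
#' @param which \code{"signal"} or \code{"noise"}.
#' @param distance \code{"axis"} or \code{"euclidean"}.
#' @return list with \code{pearson_r}, \code{p}, \code{slope} (correlation
#'   units per micrometre), \code{n}; degenerate distances are flagged.
#' @export
correlationDistanceTrend <- function(pairs, which = c("signal", "noise"),
                                     distance = c("axis", "euclidean")) {
  which <- match.arg(which)
  distance <- match.arg(distance)
  v <- pairs[[paste0(which, "_r")]]
  d <- pairs[[if (distance == "axis") "axis_distance_um" else "distance_um"]]
  keep <- is.finite(v) & is.finite(d)
  v <- v[keep]; d <- d[keep]
  if (length(v) < 3L) stop("need at least 3 pairs")
  if (stats::sd(d) == 0 || stats::sd(v) == 0)
    return(list(pearson_r = NA_real_, p = NA_real_, slope = 0,
                n = length(v), degenerate = TRUE))
  ct <- stats::cor.test(v, d)
  fit <- stats::lm(v ~ d)
  list(pearson_r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]), n = length(v),
       degenerate = FALSE)
}

#' Mean correlation for each combination of FRA classes
#'
#' Mean signal (or noise) correlation for pairs of neurons across all nine
#' combinations of the three FRA classes, mirrored into a symmetric 3x3
#' matrix (pairs are unordered). Empty combinations are NA.
#'
#' @inheritParams correlationDistanceTrend
#' @param classes class labels ordering the matrix.
#' @return symmetric 3x3 matrix of means.
#' @export
classPairMatrix <- function(pairs, which = c("signal", "noise"),
                            classes = c("single", "double", "complex")) {
  which <- match.arg(which)
  v <- pairs[[paste0(which, "_r")]]
  out <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(classes, classes))
  for (i in seq_along(classes)) {
    for (j in i:length(classes)) {
      sel <- (pairs$label_a == classes[i] & pairs$label_b == classes[j]) |
        (pairs$label_a == classes[j] & pairs$label_b == classes[i])
      if (any(sel)) out[i, j] <- out[j, i] <- mean(v[sel], na.rm = TRUE)
    }
  }
  out
}

## expand an [n_freq x n_level] matrix of cell means to the full
## [n_freq x n_level x n_trial] tensor
replicateCells <- function(cellmeans, n_trial) {
  array(rep(as.vector(cellmeans), n_trial),
        dim = c(dim(cellmeans), n_trial))
}
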