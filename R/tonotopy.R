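#' Local best-frequency deviation within a field
#'
#' For each analysed neuron, the absolute octave difference between its BF
#' and the centre (median by default) BF of every *other* neuron in the
#' reference set within the same imaging field (a leave-one-out centre).
#' The reference set is either all neurons of the same FRA class
#' (\code{reference = "same_class"}) or all frequency-sensitive neurons.
#' Deviations are also expressed per millimetre of cortex by dividing by
#' the field extent.
#'
#' Fields contributing fewer than \code{min_n} neurons to a reference set
#' are excluded from that analysis (the inclusion rule of at least three
#' neurons per class).
#'
#' @param classifications data.frame from [classifyNeurons()] (or any frame
#'   with neuron_id, label, bf_hz for sensitive neurons).
#' @param extent_mm field extent used for the per-mm normalization,
#'   \code{max(width, height)} in mm (see [fieldExtentMm()]).
#' @param reference \code{"same_class"} or \code{"all_sensitive"}.
#' @param center \code{"median"} (default) or \code{"mean"}; the centre is
#'   taken on log2-frequency.
#' @param min_n minimum reference-set size (default 3).
#' @return data.frame with neuron_id, label, bf_hz, deviation_oct,
#'   deviation_oct_per_mm; neurons whose reference set is too small are
#'   dropped, with the excluded classes recorded in the
#'   \code{"excluded_classes"} attribute.
#' @export
localBFDeviation <- function(classifications, extent_mm,
                             reference = c("same_class", "all_sensitive"),
                             center = c("median", "mean"),
                             min_n = 3L) {
  reference <- match.arg(reference)
  center <- match.arg(center)
  cfun <- if (center == "median") stats::median else mean
  d <- classifications[classifications$is_sensitive %||% TRUE &
                         !is.na(classifications$bf_hz), , drop = FALSE]
  excluded <- character()
  rows <- lapply(seq_len(nrow(d)), function(i) {
    ref <- if (reference == "same_class")
      d[d$label == d$label[i], , drop = FALSE] else d
    if (nrow(ref) < min_n) {
      excluded <<- union(excluded, d$label[i])
      return(NULL)
    }
    others <- ref$bf_hz[ref$neuron_id != d$neuron_id[i]]
    dev <- abs(log2(d$bf_hz[i]) - cfun(log2(others)))
    data.frame(neuron_id = d$neuron_id[i], label = d$label[i],
               bf_hz = d$bf_hz[i], deviation_oct = dev,
               deviation_oct_per_mm = dev / extent_mm)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(neuron_id = character(), label = character(),
                      bf_hz = numeric(), deviation_oct = numeric(),
                      deviation_oct_per_mm = numeric())
  attr(out, "excluded_classes") <- excluded
  out
}

#' Field extent for per-millimetre normalization
#'
#' The larger of field width and height, in millimetres.
#' @param field an [ImagingField-class].
#' @export
fieldExtentMm <- function(field) max(fieldExtent(field)) / 1000

#' Percentage of BFs within the species-expected range
#'
#' The span of best frequencies a perfect tonotopic gradient could produce
#' across one imaging field is \code{slope * diameter} octaves. Centring
#' that span on the field's central BF (median by default), this returns
#' the percentage of neurons whose BF falls within half that span of the
#' centre, i.e. \code{|log2(BF / BF_center)| <= slope * diameter / 2} --
#' a tonotopic-variability measure directly comparable across species with
#' different hearing ranges and axis lengths.
#'
#' @param bfs_hz best frequencies of the analysed subset within one field.
#' @param slope_oct_per_mm species tonotopic slope (see [tonotopicSlope()]).
#' @param diameter_mm imaging-field diameter, \code{max(width, height)} mm.
#' @param center \code{"median"} or \code{"mean"} (on log2-frequency).
#' @return percentage in [0, 100], or NA for an empty subset.
#' @examples
#' expectedRangeFraction(c(8000, 9000, 30000), 2.93, 0.3)
#' @export
expectedRangeFraction <- function(bfs_hz, slope_oct_per_mm, diameter_mm,
                                  center = c("median", "mean")) {
  center <- match.arg(center)
  bfs_hz <- bfs_hz[!is.na(bfs_hz)]
  if (!length(bfs_hz)) return(NA_real_)
  cfun <- if (center == "median") stats::median else mean
  half_width <- slope_oct_per_mm * diameter_mm / 2
  dev <- abs(log2(bfs_hz) - cfun(log2(bfs_hz)))
  100 * sum(dev <= half_width) / length(bfs_hz)
}

#' Equal-n bootstrap of per-class mean local deviation
#'
#' Controls for unequal class sizes: on each bootstrap draw,
#' \code{n_per_class} neurons per class are sampled without replacement
#' within every field (fields with fewer are excluded for that class), the
#' leave-one-out deviations are recomputed on the subsample, and the
#' per-class mean deviation is recorded.
#'
#' @param field_classifications list of per-field classification frames
#'   (from [classifyNeurons()]).
#' @param extents_mm per-field extents (mm), recycled if length 1.
#' @param n_per_class neurons sampled per class per field (>= 3).
#' @param n_boot number of bootstrap draws.
#' @param seed RNG seed.
#' @param classes classes to analyse.
#' @param center centre statistic, as in [localBFDeviation()].
#' @return list with \code{draws} (matrix n_boot x classes of mean
#'   deviation_oct), \code{ci} (2.5/50/97.5 percentiles per class) and
#'   \code{n_fields_used} per class.
#' @export
equalNBootstrap <- function(field_classifications, extents_mm,
                            n_per_class = 3L, n_boot = 200L, seed = 1,
                            classes = c("single", "double", "complex"),
                            center = "median") {
  if (n_per_class < 3L) stop("n_per_class must be >= 3")
  n_fld <- length(field_classifications)
  extents_mm <- rep_len(extents_mm, n_fld)
  withSeed(seed, {
    draws <- matrix(NA_real_, n_boot, length(classes),
                    dimnames = list(NULL, classes))
    used <- integer(length(classes))
    names(used) <- classes
    for (b in seq_len(n_boot)) {
      devs <- stats::setNames(vector("list", length(classes)), classes)
      for (k in seq_len(n_fld)) {
        cl <- field_classifications[[k]]
        cl <- cl[cl$is_sensitive & !is.na(cl$label), , drop = FALSE]
        for (cls in classes) {
          idx <- which(cl$label == cls)
          if (length(idx) < n_per_class) next
          sub <- cl[sample(idx, n_per_class), , drop = FALSE]
          ld <- localBFDeviation(sub, extents_mm[k], reference = "same_class",
                                 center = center, min_n = n_per_class)
          devs[[cls]] <- c(devs[[cls]], ld$deviation_oct)
          if (b == 1L) used[cls] <- used[cls] + 1L
        }
      }
      draws[b, ] <- vapply(devs, function(v)
        if (length(v)) mean(v) else NA_real_, numeric(1))
    }
    ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                na.rm = TRUE)
    list(draws = draws, ci = ci, n_fields_used = used)
  })
}

#' Fit the global tonotopic gradient
#'
#' Least-squares fit of log2(BF) against position along the tonotopic axis
#' -- the linearized form of a single-term exponential
#' \code{BF(x) = a * exp(b * x)} -- together with the Pearson correlation
#' of log2(BF) with position and the per-neuron residuals in octaves.
#'
#' @param axis_positions_mm positions along the tonotopic axis (mm).
#' @param bfs_hz best frequencies (> 0), same length.
#' @return list with \code{a}, \code{b} (exponential parameters),
#'   \code{slope_oct_per_mm}, \code{intercept_log2}, \code{pearson_r},
#'   \code{p}, \code{residuals_oct}, \code{fitted_log2} and a
#'   \code{degenerate} flag (constant x or constant BF).
#' @export
fitGlobalGradient <- function(axis_positions_mm, bfs_hz) {
  keep <- is.finite(axis_positions_mm) & is.finite(bfs_hz) & bfs_hz > 0
  x <- axis_positions_mm[keep]
  y <- log2(bfs_hz[keep])
  if (length(x) < 3L) stop("need at least 3 points to fit a gradient")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(a = NA_real_, b = NA_real_, slope_oct_per_mm = NA_real_,
                intercept_log2 = NA_real_, pearson_r = NA_real_,
                p = NA_real_, residuals_oct = rep(NA_real_, length(x)),
                fitted_log2 = rep(NA_real_, length(x)), degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(y, x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  list(a = 2^intercept, b = slope * log(2),
       slope_oct_per_mm = slope, intercept_log2 = intercept,
       pearson_r = unname(ct$estimate), p = ct$p.value,
       residuals_oct = abs(stats::residuals(fit)),
       fitted_log2 = unname(stats::fitted(fit)), degenerate = FALSE)
}

#' Compare gradient residuals between FRA classes
#'
#' Welch two-sample t-tests on the absolute residuals (octaves) around the
#' fitted global gradient, for every pair of classes.
#'
#' @param residuals_oct absolute residuals from [fitGlobalGradient()].
#' @param labels FRA class per residual.
#' @return data.frame with one row per class pair: group_a, group_b, n_a,
#'   n_b, mean_a, mean_b, t, p. Groups with fewer than 2 residuals are
#'   excluded.
#' @export
compareResiduals <- function(residuals_oct, labels) {
  stopifnot(length(residuals_oct) == length(labels))
  keep <- is.finite(residuals_oct) & !is.na(labels)
  residuals_oct <- residuals_oct[keep]
  labels <- labels[keep]
  groups <- names(which(table(labels) >= 2L))
  if (length(groups) < 2L)
    return(data.frame(group_a = character(), group_b = character(),
                      n_a = integer(), n_b = integer(), mean_a = numeric(),
                      mean_b = numeric(), t = numeric(), p = numeric()))
  pairs <- utils::combn(sort(groups), 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- residuals_oct[labels == pairs[1, k]]
    b <- residuals_oct[labels == pairs[2, k]]
    tt <- stats::t.test(a, b)
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), p = tt$p.value)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
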