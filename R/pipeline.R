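#' Run the full tonotopy analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-neuron receptive-field analysis ->
#' local and species-normalized tonotopy metrics -> global gradient fit ->
#' pairwise correlations -> group statistics, and optionally writes the
#' result tables and a machine-readable summary.
#'
#' The configuration is a plain list (fully serializable, so a run is
#' reproducible from config + seed alone):
#' \describe{
#'   \item{species}{preset name or [SpeciesParams-class] (default
#'     "ferret").}
#'   \item{n_fields, n_neurons}{cohort size when simulating (defaults 10,
#'     60).}
#'   \item{class_mix, bf_scatter_oct, noise, neuropil_coeff}{passed to
#'     [generateField()].}
#'   \item{input_dirs}{character vector of field directories (from
#'     [writeField()]); when given, fields are loaded instead of
#'     simulated.}
#'   \item{alpha}{sensitivity significance level (default 0.05).}
#'   \item{center}{"median" (default) or "mean" centre statistic.}
#'   \item{neuropil_r}{if non-NULL, neuropil-correct stored responses with
#'     this coefficient before analysis.}
#'   \item{seed}{master seed (default 1).}
#'   \item{out_dir}{if non-NULL, write classifications.csv,
#'     field_metrics.csv, pairs.csv and summary.json there.}
#' }
#'
#' @param config configuration list as above.
#' @return list with \code{classifications}, \code{deviations},
#'   \code{field_metrics}, \code{gradient} (fit + residual t-tests),
#'   \code{pairs}, \code{correlation_stats}, \code{class_stats} and
#'   \code{summary} (the content of summary.json).
#' @export
runPipeline <- function(config = list()) {
  cfg <- utils::modifyList(
    list(species = "ferret", n_fields = 10L, n_neurons = 60L,
         class_mix = NULL, bf_scatter_oct = NULL, noise = NULL,
         neuropil_coeff = 0, input_dirs = NULL, alpha = 0.05,
         center = "median", neuropil_r = NULL, seed = 1L,
         out_dir = NULL),
    config)
  species <- if (is.character(cfg$species)) speciesPreset(cfg$species)
  else cfg$species

  ## stage 1: obtain fields
  fields <- if (!is.null(cfg$input_dirs)) {
    lapply(cfg$input_dirs, readField)
  } else {
    args <- list(species = species, n_fields = cfg$n_fields,
                 n_neurons = cfg$n_neurons, seed = cfg$seed,
                 neuropil_coeff = cfg$neuropil_coeff)
    for (nm in c("class_mix", "bf_scatter_oct", "noise"))
      if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
    do.call(generateCohort, args)
  }
  message("pipeline: ", length(fields), " field(s)")

  ## stage 2: per-neuron analysis
  class_list <- lapply(fields, classifyNeurons, alpha = cfg$alpha,
                       neuropil_r = cfg$neuropil_r)
  classifications <- do.call(rbind, Map(function(cl, fld) {
    cbind(field_id = fieldId(fld), cl)
  }, class_list, fields))
  n_deg <- sum(classifications$degenerate)
  if (n_deg > 0)
    warning(n_deg, " neuron(s) flagged degenerate in the sensitivity test")

  ## stage 3: local deviations and species-normalized range fractions
  extents <- vapply(fields, fieldExtentMm, numeric(1))
  slope_sp <- tonotopicSlope(species)
  classes <- c("single", "double", "complex")
  dev_list <- Map(function(cl, ext, fld) {
    ld <- localBFDeviation(cl, ext, reference = "same_class",
                           center = cfg$center)
    if (nrow(ld)) cbind(field_id = fieldId(fld), ld) else NULL
  }, class_list, extents, fields)
  deviations <- do.call(rbind, dev_list)
  field_metrics <- do.call(rbind, Map(function(cl, ext, fld) {
    sens <- cl[cl$is_sensitive & !is.na(cl$label), , drop = FALSE]
    do.call(rbind, lapply(c(classes, "all"), function(cls) {
      bfs <- if (cls == "all") sens$bf_hz else sens$bf_hz[sens$label == cls]
      ld <- if (is.null(deviations)) NULL else
        deviations[deviations$field_id == fieldId(fld) &
                     (cls == "all" | deviations$label == cls), ]
      data.frame(field_id = fieldId(fld), class = cls, n = length(bfs),
                 mean_deviation_oct = if (!is.null(ld) && nrow(ld))
                   mean(ld$deviation_oct) else NA_real_,
                 mean_deviation_oct_per_mm = if (!is.null(ld) && nrow(ld))
                   mean(ld$deviation_oct_per_mm) else NA_real_,
                 expected_range_pct = expectedRangeFraction(
                   bfs, slope_sp, ext, center = cfg$center))
    }))
  }, class_list, extents, fields))

  ## stage 4: global gradient on single-peaked neurons, residuals per class
  sens <- classifications[classifications$is_sensitive &
                            !is.na(classifications$label), , drop = FALSE]
  gradient <- NULL
  if (sum(sens$label == "single") >= 3L) {
    s <- sens[sens$label == "single", ]
    fit <- fitGlobalGradient(s$axis_mm, s$bf_hz)
    fit_all <- fitGlobalGradient(sens$axis_mm, sens$bf_hz)
    res_tests <- compareResiduals(fit_all$residuals_oct, sens$label)
    gradient <- list(single = fit, all = fit_all,
                     residual_tests = res_tests)
  }

  ## stage 5: pairwise correlations
  pairs <- do.call(rbind, Map(function(fld, cl) {
    p <- pairCorrelations(fld, cl)
    if (nrow(p)) cbind(field_id = fieldId(fld), p) else NULL
  }, fields, class_list))
  correlation_stats <- NULL
  if (!is.null(pairs) && nrow(pairs) >= 3L) {
    correlation_stats <- list(
      signal = correlationClassANOVA(pairs, "signal"),
      noise = correlationClassANOVA(pairs, "noise"),
      signal_matrix = classPairMatrix(pairs, "signal"),
      noise_matrix = classPairMatrix(pairs, "noise"),
      signal_distance = tryCatch(
        correlationDistanceTrend(pairs, "signal", "axis"),
        error = function(e) NULL),
      noise_distance = tryCatch(
        correlationDistanceTrend(pairs, "noise", "euclidean"),
        error = function(e) NULL))
  }

  ## stage 6: group statistics and summary
  class_stats <- classGroupStats(classifications)
  k <- sum(classifications$is_sensitive)
  n <- nrow(classifications)
  cls_counts <- table(factor(sens$label, levels = classes))
  mean_dev <- if (is.null(deviations)) rep(NA_real_, 3) else
    vapply(classes, function(cls)
      mean(deviations$deviation_oct[deviations$label == cls]), numeric(1))
  mean_dev_mm <- if (is.null(deviations)) rep(NA_real_, 3) else
    vapply(classes, function(cls)
      mean(deviations$deviation_oct_per_mm[deviations$label == cls]),
      numeric(1))
  range_pct <- vapply(c(classes, "all"), function(cls) {
    v <- field_metrics$expected_range_pct[field_metrics$class == cls &
                                            field_metrics$n >= 3]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  summary_json <- list(
    species = species@name,
    n_fields = length(fields),
    n_neurons = n,
    n_sensitive = k,
    sensitive_line = formatCountLine(k, n),
    sensitive_pct = round(100 * k / n, 2),
    class_counts = as.list(cls_counts),
    class_pct_of_sensitive = as.list(round(100 * cls_counts /
                                             max(1, sum(cls_counts)), 2)),
    mean_deviation_oct = as.list(stats::setNames(mean_dev, classes)),
    mean_deviation_oct_per_mm = as.list(stats::setNames(mean_dev_mm,
                                                        classes)),
    expected_range_pct = as.list(range_pct),
    gradient = if (!is.null(gradient)) list(
      slope_oct_per_mm = gradient$single$slope_oct_per_mm,
      pearson_r = gradient$single$pearson_r,
      p = gradient$single$p) else NULL,
    signal_correlation_means = if (!is.null(correlation_stats))
      as.list(correlation_stats$signal$means) else NULL,
    noise_correlation_means = if (!is.null(correlation_stats))
      as.list(correlation_stats$noise$means) else NULL,
    seed = cfg$seed)

  result <- list(classifications = classifications, deviations = deviations,
                 field_metrics = field_metrics, gradient = gradient,
                 pairs = pairs, correlation_stats = correlation_stats,
                 class_stats = class_stats, summary = summary_json)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(classifications,
                     file.path(cfg$out_dir, "classifications.csv"),
                     row.names = FALSE)
    utils::write.csv(field_metrics,
                     file.path(cfg$out_dir, "field_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(pairs))
      utils::write.csv(pairs, file.path(cfg$out_dir, "pairs.csv"),
                       row.names = FALSE)
    jsonlite::write_json(summary_json,
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  result
}
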