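#' @rdname StimulusGrid-class
#' @param object a [StimulusGrid-class].
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname StimulusGrid-class
#' @export
setMethod("frequencies", "StimulusGrid", function(object) object@frequencies_hz)

#' @rdname StimulusGrid-class
#' @export
setGeneric("soundLevels", function(object) standardGeneric("soundLevels"))

#' @rdname StimulusGrid-class
#' @export
setMethod("soundLevels", "StimulusGrid", function(object) object@levels_db)

#' @rdname StimulusGrid-class
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname StimulusGrid-class
#' @export
setMethod("nTrials", "StimulusGrid", function(object) object@n_trials)

setMethod("show", "StimulusGrid", function(object) {
  f <- object@frequencies_hz
  cat(sprintf(
    "StimulusGrid: %d frequencies (%.3g-%.3g kHz), %d levels (%g-%g dB SPL), %d trials, %g ms tones\n",
    length(f), min(f) / 1000, max(f) / 1000,
    length(object@levels_db), min(object@levels_db), max(object@levels_db),
    object@n_trials, object@stim_duration_ms))
})

#' Tonotopic slope of a species
#'
#' Octaves of best frequency traversed per millimetre of cortex if the full
#' hearing range maps linearly (in log-frequency) onto the A1 tonotopic
#' axis: \code{log2(hearing_hi / hearing_lo) / axis_length_mm}.
#'
#' @param object a [SpeciesParams-class].
#' @return slope in octaves per millimetre.
#' @examples
#' tonotopicSlope(mouseParams())   # 4.91 oct/mm
#' tonotopicSlope(ferretParams())  # 2.93 oct/mm
#' @export
setGeneric("tonotopicSlope", function(object) standardGeneric("tonotopicSlope"))

#' @rdname tonotopicSlope
#' @export
setMethod("tonotopicSlope", "SpeciesParams", function(object) {
  speciesSlope(object@hearing_lo_hz, object@hearing_hi_hz,
               object@axis_length_mm)
})

#' Tonotopic map slope from hearing range and axis length
#'
#' @param hearing_lo_hz,hearing_hi_hz audible range bounds (Hz), hi > lo > 0.
#' @param axis_length_mm tonotopic axis length (mm), > 0.
#' @return slope in octaves per millimetre, \code{log2(hi/lo)/length}.
#' @examples
#' speciesSlope(2000, 60000, 1.0)  # mouse, 4.91
#' speciesSlope(36, 44000, 3.5)    # ferret, 2.93
#' @export
speciesSlope <- function(hearing_lo_hz, hearing_hi_hz, axis_length_mm) {
  if (hearing_lo_hz <= 0 || hearing_hi_hz <= hearing_lo_hz ||
      axis_length_mm <= 0)
    stop("need hearing_hi_hz > hearing_lo_hz > 0 and axis_length_mm > 0")
  log2(hearing_hi_hz / hearing_lo_hz) / axis_length_mm
}

setMethod("show", "SpeciesParams", function(object) {
  cat(sprintf(
    "SpeciesParams '%s': hearing %.3g Hz - %.3g kHz, axis %.2g mm, slope %.2f oct/mm\n",
    object@name, object@hearing_lo_hz, object@hearing_hi_hz / 1000,
    object@axis_length_mm, tonotopicSlope(object)))
})

#' @describeIn ImagingField-class the field's [StimulusGrid-class].
#' @param object an [ImagingField-class].
#' @export
setGeneric("stimulusGrid", function(object) standardGeneric("stimulusGrid"))

#' @rdname ImagingField-class
#' @export
setMethod("stimulusGrid", "ImagingField",
          function(object) metadata(object)$grid)

#' @describeIn ImagingField-class the field's [SpeciesParams-class].
#' @export
setGeneric("speciesParams", function(object) standardGeneric("speciesParams"))

#' @rdname ImagingField-class
#' @export
setMethod("speciesParams", "ImagingField",
          function(object) metadata(object)$species)

#' @describeIn ImagingField-class field identifier.
#' @export
setGeneric("fieldId", function(object) standardGeneric("fieldId"))

#' @rdname ImagingField-class
#' @export
setMethod("fieldId", "ImagingField", function(object) metadata(object)$field_id)

#' @describeIn ImagingField-class field width and height in micrometres.
#' @export
setGeneric("fieldExtent", function(object) standardGeneric("fieldExtent"))

#' @rdname ImagingField-class
#' @export
setMethod("fieldExtent", "ImagingField", function(object) {
  md <- metadata(object)
  c(width_um = md$width_um, height_um = md$height_um)
})

#' @describeIn ImagingField-class field-centre coordinate on the tonotopic
#'   axis (mm).
#' @export
setGeneric("axisPosition", function(object) standardGeneric("axisPosition"))

#' @rdname ImagingField-class
#' @export
setMethod("axisPosition", "ImagingField",
          function(object) metadata(object)$axis_position_mm)

#' @describeIn ImagingField-class neuron coordinates; a data.frame with
#'   neuron_id, x_um, y_um and axis_mm (each neuron's own coordinate along
#'   the global tonotopic axis, obtained by projecting its position onto the
#'   axis direction).
#' @export
setGeneric("neuronPositions", function(object) standardGeneric("neuronPositions"))

#' @rdname ImagingField-class
#' @export
setMethod("neuronPositions", "ImagingField", function(object) {
  rd <- rowData(object)
  md <- metadata(object)
  proj_um <- (rd$x_um - md$width_um / 2) * cos(md$axis_angle) +
    (rd$y_um - md$height_um / 2) * sin(md$axis_angle)
  data.frame(neuron_id = rd$neuron_id, x_um = rd$x_um, y_um = rd$y_um,
             axis_mm = md$axis_position_mm + proj_um / 1000)
})

#' Trial response tensor of one neuron
#'
#' Reshapes one row of the \code{"responses"} assay back into the
#' \code{[n_freq x n_level x n_trial]} tensor implied by the stimulus grid.
#'
#' @param field an [ImagingField-class].
#' @param neuron neuron index or neuron_id.
#' @param assay_name which assay to reshape (default \code{"responses"}).
#' @return numeric array \code{[n_freq x n_level x n_trial]} with dimnames
#'   taken from the grid.
#' @export
responseTensor <- function(field, neuron, assay_name = "responses") {
  grid <- stimulusGrid(field)
  if (is.character(neuron))
    neuron <- match(neuron, rowData(field)$neuron_id)
  x <- assay(field, assay_name)[neuron, ]
  array(x,
        dim = c(length(grid@frequencies_hz), length(grid@levels_db),
                grid@n_trials),
        dimnames = list(as.character(grid@frequencies_hz),
                        as.character(grid@levels_db), NULL))
}

#' Generative ground truth of a synthetic field
#'
#' @param field an [ImagingField-class] produced by [generateField()].
#' @return data.frame of per-neuron ground truth, or NULL for recorded data.
#' @export
groundTruth <- function(field) {
  rd <- as.data.frame(rowData(field))
  if (!"true_class" %in% colnames(rd)) return(NULL)
  rd[, c("neuron_id", "true_class", "true_bf_hz", "true_peak2_hz",
         "true_bandwidth_oct", "peak_gain", "shared_noise_loading",
         "neuropil_coeff")]
}

setMethod("show", "ImagingField", function(object) {
  md <- metadata(object)
  cat(sprintf("ImagingField '%s' (%s): %d neurons, %g x %g um, axis %.2f mm\n",
              md$field_id, md$species@name, nrow(object),
              md$width_um, md$height_um, md$axis_position_mm))
  show(md$grid)
})
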