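#' @import methods
#' @importFrom S4Vectors metadata DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Stimulus grid of a pure-tone mapping recording
#'
#' The frequency x level x repetition design used to probe frequency
#' receptive fields: pure tones at ascending frequencies and sound levels,
#' each frequency/level combination repeated \code{n_trials} times.
#'
#' @slot frequencies_hz numeric, strictly ascending tone frequencies (Hz).
#' @slot levels_db numeric, ascending sound levels (dB SPL).
#' @slot n_trials integer, repetitions per frequency/level combination.
#' @slot stim_duration_ms numeric, tone duration in milliseconds.
#'
#' @seealso [StimulusGrid()], [ferretGrid()], [mouseGrid()]
#' @exportClass StimulusGrid
setClass("StimulusGrid",
  representation(
    frequencies_hz = "numeric",
    levels_db = "numeric",
    n_trials = "integer",
    stim_duration_ms = "numeric"
  )
)

setValidity("StimulusGrid", function(object) {
  f <- object@frequencies_hz
  msg <- character()
  if (length(f) < 2L)
    msg <- c(msg, "need at least 2 tone frequencies")
  if (any(f <= 0))
    msg <- c(msg, "frequencies must be positive")
  if (is.unsorted(f, strictly = TRUE))
    msg <- c(msg, "frequencies must be strictly ascending")
  if (length(object@levels_db) < 1L)
    msg <- c(msg, "need at least 1 sound level")
  if (is.unsorted(object@levels_db, strictly = TRUE))
    msg <- c(msg, "levels must be strictly ascending")
  if (length(object@n_trials) != 1L || object@n_trials < 2L)
    msg <- c(msg, "n_trials must be a single integer >= 2 (trial variance must be computable)")
  if (object@stim_duration_ms <= 0)
    msg <- c(msg, "stim_duration_ms must be positive")
  if (length(msg)) msg else TRUE
})

#' Species-level tonotopic axis parameters
#'
#' Hearing range and A1 tonotopic-axis length for one species. The tonotopic
#' slope in octaves per millimetre is a derived quantity,
#' \code{log2(hearing_hi / hearing_lo) / axis_length_mm}, returned by
#' [tonotopicSlope()]; it is never stored independently, so it cannot drift
#' out of sync with the range it is derived from.
#'
#' @slot name character species label, e.g. \code{"ferret"}.
#' @slot hearing_lo_hz,hearing_hi_hz numeric bounds of the audible range (Hz).
#' @slot axis_length_mm numeric length of the A1 tonotopic axis (mm).
#'
#' @seealso [SpeciesParams()], [ferretParams()], [mouseParams()],
#'   [speciesSlope()]
#' @exportClass SpeciesParams
setClass("SpeciesParams",
  representation(
    name = "character",
    hearing_lo_hz = "numeric",
    hearing_hi_hz = "numeric",
    axis_length_mm = "numeric"
  )
)

setValidity("SpeciesParams", function(object) {
  msg <- character()
  if (object@hearing_lo_hz <= 0)
    msg <- c(msg, "hearing_lo_hz must be positive")
  if (object@hearing_hi_hz <= object@hearing_lo_hz)
    msg <- c(msg, "hearing_hi_hz must exceed hearing_lo_hz")
  if (object@axis_length_mm <= 0)
    msg <- c(msg, "axis_length_mm must be positive")
  if (length(msg)) msg else TRUE
})

#' A simultaneously imaged population of neurons
#'
#' An \code{ImagingField} holds one two-photon imaging field: the trial-by-
#' trial evoked responses of every neuron recorded simultaneously within a
#' rectangular patch of cortex, together with the stimulus grid, the neuron
#' coordinates, the species parameters and the field's position along the
#' global tonotopic axis.
#'
#' The class extends [SummarizedExperiment::SummarizedExperiment]: rows are
#' neurons (with coordinates and, for synthetic fields, ground truth in
#' \code{rowData}), columns are single stimulus presentations (with
#' \code{freq_hz}, \code{level_db} and \code{trial} in \code{colData}), and
#' the \code{"responses"} assay stores the nonnegative evoked event-rate of
#' each neuron on each presentation. Column order is frequency-fastest, so
#' [responseTensor()] can reshape a row back into the
#' frequency x level x trial tensor without a lookup.
#'
#' Field geometry, the [StimulusGrid-class], the [SpeciesParams-class] and
#' (for synthetic fields) the common neuropil signal live in
#' \code{metadata()}.
#'
#' @seealso [ImagingField()], [generateField()], [responseTensor()],
#'   [classifyNeurons()]
#' @exportClass ImagingField
setClass("ImagingField", contains = "SummarizedExperiment")

setValidity("ImagingField", function(object) {
  md <- metadata(object)
  msg <- character()
  required <- c("field_id", "grid", "species", "width_um", "height_um",
                "axis_position_mm", "axis_angle")
  missing_md <- setdiff(required, names(md))
  if (length(missing_md))
    return(paste("missing metadata:", paste(missing_md, collapse = ", ")))
  grid <- md$grid
  if (!is(grid, "StimulusGrid"))
    return("metadata$grid must be a StimulusGrid")
  if (!is(md$species, "SpeciesParams"))
    return("metadata$species must be a SpeciesParams")
  n_cell <- length(grid@frequencies_hz) * length(grid@levels_db) * grid@n_trials
  if (ncol(object) != n_cell)
    msg <- c(msg, sprintf("ncol (%d) does not match grid (%d presentations)",
                          ncol(object), n_cell))
  cd <- colData(object)
  if (!all(c("freq_hz", "level_db", "trial") %in% colnames(cd)))
    msg <- c(msg, "colData must contain freq_hz, level_db, trial")
  rd <- rowData(object)
  if (!all(c("x_um", "y_um") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain x_um, y_um")
  else {
    if (any(rd$x_um < 0 | rd$x_um > md$width_um) ||
        any(rd$y_um < 0 | rd$y_um > md$height_um))
      msg <- c(msg, "neuron coordinates must lie within the field extent")
  }
  if (!"responses" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'responses' is required")
  else if (any(assay(object, "responses") < 0))
    msg <- c(msg, "responses must be nonnegative")
  if (md$axis_position_mm < 0 ||
      md$axis_position_mm > md$species@axis_length_mm)
    msg <- c(msg, "axis_position_mm must lie within the species axis length")
  if (length(msg)) msg else TRUE
})
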