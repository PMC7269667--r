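#' Construct a stimulus grid
#'
#' @param frequencies_hz strictly ascending tone frequencies (Hz).
#' @param levels_db ascending sound levels (dB SPL).
#' @param n_trials repetitions per frequency/level combination (>= 2).
#' @param stim_duration_ms tone duration (ms).
#'
#' @return A [StimulusGrid-class] object.
#' @examples
#' StimulusGrid(c(4000, 8000, 16000), c(50, 70), n_trials = 10)
#' @export
StimulusGrid <- function(frequencies_hz, levels_db, n_trials,
                         stim_duration_ms = 100) {
  new("StimulusGrid",
      frequencies_hz = as.numeric(frequencies_hz),
      levels_db = as.numeric(levels_db),
      n_trials = as.integer(n_trials),
      stim_duration_ms = as.numeric(stim_duration_ms))
}

#' Ferret-like pure-tone stimulus grid
#'
#' Tones at 0.25-octave spacing spanning just under five octaves from 1 kHz,
#' at 30--90 dB SPL in 20 dB steps, 12 repetitions of a 500 ms tone --
#' representative of the per-animal designs used for ferret A1 mapping.
#'
#' @return A [StimulusGrid-class].
#' @export
ferretGrid <- function() {
  StimulusGrid(frequencies_hz = 1000 * 2^(seq(0, 4.75, by = 0.25)),
               levels_db = c(30, 50, 70, 90),
               n_trials = 12L,
               stim_duration_ms = 500)
}

#' Mouse-like pure-tone stimulus grid
#'
#' 18 tones log-spaced from 1.9 to 50 kHz at four levels (40--100 dB SPL),
#' 10 repetitions of a 100 ms tone.
#'
#' @return A [StimulusGrid-class].
#' @export
mouseGrid <- function() {
  StimulusGrid(frequencies_hz = 1900 * 2^seq(0, log2(50 / 1.9), length.out = 18),
               levels_db = c(40, 60, 80, 100),
               n_trials = 10L,
               stim_duration_ms = 100)
}

#' Construct species parameters
#'
#' @param name species label.
#' @param hearing_lo_hz,hearing_hi_hz audible range bounds (Hz).
#' @param axis_length_mm A1 tonotopic axis length (mm).
#'
#' @return A [SpeciesParams-class] object.
#' @examples
#' tonotopicSlope(SpeciesParams("mouse", 2000, 60000, 1))
#' @export
SpeciesParams <- function(name, hearing_lo_hz, hearing_hi_hz, axis_length_mm) {
  new("SpeciesParams", name = name,
      hearing_lo_hz = as.numeric(hearing_lo_hz),
      hearing_hi_hz = as.numeric(hearing_hi_hz),
      axis_length_mm = as.numeric(axis_length_mm))
}

#' Mouse A1 parameters
#'
#' C57BL/6 hearing range 2--60 kHz mapped over a ~1 mm tonotopic axis,
#' giving a gradient slope of 4.91 oct/mm.
#' @return A [SpeciesParams-class].
#' @export
mouseParams <- function() SpeciesParams("mouse", 2000, 60000, 1.0)

#' Ferret A1 parameters
#'
#' Hearing range ~36 Hz -- 44 kHz mapped over a ~3.5 mm tonotopic axis,
#' giving a gradient slope of 2.93 oct/mm.
#' @return A [SpeciesParams-class].
#' @export
ferretParams <- function() SpeciesParams("ferret", 36, 44000, 3.5)

#' Look up a species preset by name
#' @param name \code{"ferret"} or \code{"mouse"}.
#' @return A [SpeciesParams-class].
#' @export
speciesPreset <- function(name) {
  switch(match.arg(name, c("ferret", "mouse")),
         ferret = ferretParams(),
         mouse = mouseParams())
}

#' Assemble an imaging field from response tensors
#'
#' @param responses either a matrix (neurons x presentations, columns in
#'   frequency-fastest order) or a list of per-neuron
#'   \code{[n_freq x n_level x n_trial]} arrays.
#' @param x_um,y_um neuron coordinates within the field (micrometres).
#' @param grid the [StimulusGrid-class] the responses were recorded under.
#' @param species a [SpeciesParams-class].
#' @param field_id identifier for the field.
#' @param width_um,height_um field extent (micrometres).
#' @param axis_position_mm coordinate of the field centre along the global
#'   tonotopic axis (mm).
#' @param axis_angle direction of the tonotopic axis in field coordinates
#'   (radians; 0 means the x-axis is the tonotopic axis).
#' @param neuron_id optional neuron identifiers (default \code{n1, n2, ...}).
#' @param ground_truth optional data.frame of generative ground truth, one
#'   row per neuron (attached to \code{rowData}).
#' @param neuropil optional common neuropil signal, one value per
#'   presentation.
#'
#' @return An [ImagingField-class].
#' @export
ImagingField <- function(responses, x_um, y_um, grid, species,
                         field_id = "field1",
                         width_um = 250, height_um = 250,
                         axis_position_mm = species@axis_length_mm / 2,
                         axis_angle = 0,
                         neuron_id = NULL,
                         ground_truth = NULL,
                         neuropil = NULL) {
  if (is.list(responses) && !is.matrix(responses))
    responses <- do.call(rbind, lapply(responses, as.vector))
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (is.null(neuron_id)) neuron_id <- paste0("n", seq_len(n))
  stopifnot(length(x_um) == n, length(y_um) == n)
  cd <- stimulusDesign(grid)
  if (ncol(responses) != nrow(cd))
    stop("responses have ", ncol(responses), " columns but the grid implies ",
         nrow(cd), " presentations")
  rd <- S4Vectors::DataFrame(neuron_id = neuron_id, x_um = x_um, y_um = y_um)
  if (!is.null(ground_truth)) {
    stopifnot(nrow(ground_truth) == n)
    rd <- cbind(rd, S4Vectors::DataFrame(ground_truth))
  }
  rownames(responses) <- neuron_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(responses = responses),
    rowData = rd, colData = cd,
    metadata = list(field_id = field_id, grid = grid, species = species,
                    width_um = width_um, height_um = height_um,
                    axis_position_mm = axis_position_mm,
                    axis_angle = axis_angle,
                    neuropil = neuropil))
  new("ImagingField", se)
}

#' Presentation-level design of a stimulus grid
#'
#' One row per stimulus presentation, frequency-fastest, matching the column
#' order of an [ImagingField-class].
#'
#' @param grid a [StimulusGrid-class].
#' @return A [S4Vectors::DataFrame] with columns freq_hz, level_db, trial.
#' @export
stimulusDesign <- function(grid) {
  d <- expand.grid(freq_hz = grid@frequencies_hz,
                   level_db = grid@levels_db,
                   trial = seq_len(grid@n_trials),
                   KEEP.OUT.ATTRS = FALSE)
  S4Vectors::DataFrame(d)
}
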