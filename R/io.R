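#' Write an imaging field to plain-text files
#'
#' Serializes a field into a directory of three text files:
#' \describe{
#'   \item{responses.csv}{long format, one row per neuron x presentation:
#'     neuron_id, freq_hz, level_db, trial, response.}
#'   \item{neurons.csv}{one row per neuron: neuron_id, x_um, y_um plus any
#'     ground-truth columns.}
#'   \item{field.json}{field geometry, species parameters, stimulus grid
#'     and (if present) the stored neuropil signal.}
#' }
#'
#' @param field an [ImagingField-class].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @seealso [readField()]
#' @export
writeField <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- metadata(field)
  grid <- md$grid
  cd <- as.data.frame(colData(field))
  resp <- assay(field, "responses")
  long <- data.frame(
    neuron_id = rep(rownames(resp), each = ncol(resp)),
    freq_hz = rep(cd$freq_hz, nrow(resp)),
    level_db = rep(cd$level_db, nrow(resp)),
    trial = rep(cd$trial, nrow(resp)),
    response = as.vector(t(resp)))
  utils::write.csv(long, file.path(dir, "responses.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(rowData(field)),
                   file.path(dir, "neurons.csv"), row.names = FALSE)
  sp <- md$species
  meta <- list(field_id = md$field_id,
               width_um = md$width_um, height_um = md$height_um,
               axis_position_mm = md$axis_position_mm,
               axis_angle = md$axis_angle,
               species = list(name = sp@name,
                              hearing_lo_hz = sp@hearing_lo_hz,
                              hearing_hi_hz = sp@hearing_hi_hz,
                              axis_length_mm = sp@axis_length_mm),
               grid = list(frequencies_hz = grid@frequencies_hz,
                           levels_db = grid@levels_db,
                           n_trials = grid@n_trials,
                           stim_duration_ms = grid@stim_duration_ms),
               neuropil = md$neuropil)
  jsonlite::write_json(meta, file.path(dir, "field.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an imaging field written by [writeField()]
#'
#' @param dir directory containing responses.csv, neurons.csv, field.json.
#' @return An [ImagingField-class].
#' @export
readField <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "field.json"),
                              simplifyVector = TRUE)
  grid <- StimulusGrid(meta$grid$frequencies_hz, meta$grid$levels_db,
                       meta$grid$n_trials, meta$grid$stim_duration_ms)
  species <- SpeciesParams(meta$species$name, meta$species$hearing_lo_hz,
                           meta$species$hearing_hi_hz,
                           meta$species$axis_length_mm)
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"))
  long <- utils::read.csv(file.path(dir, "responses.csv"))
  ids <- neurons$neuron_id
  n_col <- length(grid@frequencies_hz) * length(grid@levels_db) *
    grid@n_trials
  ## rebuild rows in the canonical frequency-fastest order
  fi <- match(long$freq_hz, grid@frequencies_hz)
  li <- match(long$level_db, grid@levels_db)
  if (anyNA(fi) || anyNA(li))
    stop("responses.csv contains frequencies or levels not in field.json")
  col <- fi + length(grid@frequencies_hz) *
    ((li - 1) + length(grid@levels_db) * (long$trial - 1))
  row <- match(long$neuron_id, ids)
  resp <- matrix(NA_real_, length(ids), n_col)
  resp[cbind(row, col)] <- long$response
  if (anyNA(resp)) stop("responses.csv does not cover the full grid")
  gt_cols <- setdiff(colnames(neurons), c("neuron_id", "x_um", "y_um"))
  ImagingField(resp, neurons$x_um, neurons$y_um, grid, species,
               field_id = meta$field_id,
               width_um = meta$width_um, height_um = meta$height_um,
               axis_position_mm = meta$axis_position_mm,
               axis_angle = meta$axis_angle,
               neuron_id = ids,
               ground_truth = if (length(gt_cols))
                 neurons[, gt_cols, drop = FALSE] else NULL,
               neuropil = meta$neuropil)
}
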