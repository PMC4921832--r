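#' Demultiplex sensor measurements into reflectance spectra
#'
#' Applies a trained inverse model to each row of a measurements tibble,
#' reconstructing an n-point reflectance spectrum per measurement. All
#' methods clip their raw predictions to the physical reflectance range
#' \[0, 1\].
#'
#' @param model A trained `wiener_demux` or `forest_demux`.
#' @param C A `sensor_measurements` tibble (or a single numeric p-vector).
#' @param clip Clip predictions to \[0, 1\] (default TRUE).
#' @return A `reflectance_spectra` tibble, one row per measurement.
#' @export
demultiplex <- function(model, C, clip = TRUE) {
  UseMethod("demultiplex")
}

check_channels <- function(model, C) {
  if (is.numeric(C) && is.vector(C)) {
    C <- as_measurements(matrix(C, nrow = 1), model$channels)
  }
  got <- meas_channels(C)
  if (length(got) != length(model$channels)) {
    abort_specdemux(
      sprintf("model expects %d channels (%s) but measurements have %d",
              length(model$channels), paste(model$channels, collapse = ","),
              length(got)),
      "channel_mismatch")
  }
  C
}

finish_spectra <- function(m, model, ids, clip) {
  if (!clip) {
    # raw linear predictions may stray outside [0, 1]; skip range validation
    return(new_spectra_raw(m, model$grid, ids))
  }
  as_spectra(pmin(pmax(m, 0), 1), model$grid, ids = ids)
}

#' @export
demultiplex.wiener_demux <- function(model, C, clip = TRUE) {
  C <- check_channels(model, C)
  m <- meas_matrix(C) %*% t(model$W)
  finish_spectra(m, model, C$spectrum_id, clip)
}

#' @export
demultiplex.forest_demux <- function(model, C, clip = TRUE) {
  C <- check_channels(model, C)
  m <- predict_forest_matrix(model, meas_matrix(C))
  finish_spectra(m, model, C$spectrum_id, clip)
}

#' Demultiplex an RGB image into a spectral cube
#'
#' Per-pixel application of a demultiplexer: pixels are batched through the
#' model in one call but the result is numerically identical to demultiplexing
#' each pixel separately.
#'
#' @param model A trained demultiplexer.
#' @param rgb_image A height x width x p numeric array (linear intensities).
#' @return A [spectral_cube()] on the model's grid.
#' @export
demultiplex_image <- function(model, rgb_image) {
  if (!is.array(rgb_image) || length(dim(rgb_image)) != 3 ||
      dim(rgb_image)[3] != length(model$channels)) {
    abort_specdemux(
      sprintf("image must be height x width x %d (channels %s)",
              length(model$channels), paste(model$channels, collapse = ",")),
      "channel_mismatch")
  }
  d <- dim(rgb_image)
  flat <- matrix(as.vector(rgb_image), d[1] * d[2], d[3])
  C <- as_measurements(flat, model$channels)
  sp <- demultiplex(model, C)
  m <- spectra_matrix(sp)
  spectral_cube(array(m, dim = c(d[1], d[2], ncol(m))), model$grid)
}

#' Save / load a trained demultiplexer
#'
#' Models are stored in a single-file serialized container with a format
#' version header; loading a saved model reproduces its predictions
#' bit-identically.
#'
#' @param model A `wiener_demux` or `forest_demux`.
#' @param path File path (conventionally `.rds`).
#' @return `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "demultiplexer")) {
    abort_specdemux("`model` is not a demultiplexer", "invalid_argument")
  }
  saveRDS(list(format = "specdemux-model", format_version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  container <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!is.list(container) || !identical(container$format, "specdemux-model") ||
      !inherits(container$model, "demultiplexer")) {
    abort_specdemux(
      sprintf("'%s' is not a valid demultiplexer model file", path),
      "model_format")
  }
  if (!identical(container$format_version, 1L)) {
    abort_specdemux(
      sprintf("unsupported model format version %s", container$format_version),
      "model_format")
  }
  container$model
}
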