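#' Spectral sensitivity of a color image sensor
#'
#' A sensitivity object is a tibble with a `wavelength_nm` column followed by
#' one column per color channel (typically `R`, `G`, `B`), holding the relative
#' per-channel response to unit-intensity light at each wavelength. It is the
#' p x n matrix of the linear forward model `C = S %*% lambda` that maps an
#' n-point spectrum to p channel measurements.
#'
#' @param grid A [wavelength_grid()] (or numeric wavelength vector).
#' @param matrix A p x n numeric matrix of nonnegative sensitivities, one row
#'   per channel.
#' @param channels Character vector of channel labels, length p.
#'
#' @return A tibble of class `sensor_sensitivity` with columns
#'   `wavelength_nm` and one per channel.
#' @export
sensor_sensitivity <- function(grid, matrix, channels = rownames(matrix)) {
  grid <- as_wavelength_grid(grid)
  matrix <- base::as.matrix(matrix)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(matrix)))
  if (ncol(matrix) != length(grid)) {
    abort_specdemux("sensitivity matrix must have one column per wavelength",
                    "invalid_argument")
  }
  if (length(channels) != nrow(matrix) || anyDuplicated(channels)) {
    abort_specdemux("channel labels must be unique, one per matrix row",
                    "invalid_argument")
  }
  if (any(!is.finite(matrix))) {
    abort_specdemux("sensitivities must be finite", "validation")
  }
  if (any(matrix < 0)) {
    abort_specdemux("sensitivities must be nonnegative", "validation")
  }
  if (any(apply(matrix, 1, function(r) all(r == 0)))) {
    abort_specdemux("every channel needs at least one nonzero sensitivity",
                    "validation")
  }
  out <- tibble::tibble(wavelength_nm = as.double(grid))
  for (i in seq_along(channels)) out[[channels[i]]] <- as.double(matrix[i, ])
  new_sensitivity_tbl(out)
}

new_sensitivity_tbl <- function(tbl) {
  class(tbl) <- c("sensor_sensitivity", class(tibble::tibble()))
  tbl
}

#' Extract the p x n sensitivity matrix from a sensitivity tibble
#'
#' @param S A `sensor_sensitivity` tibble.
#' @return Numeric matrix, channels in rows, wavelengths in columns.
#' @export
sens_matrix <- function(S) {
  ch <- sens_channels(S)
  m <- t(base::as.matrix(S[ch]))
  rownames(m) <- ch
  colnames(m) <- format_wl(S$wavelength_nm)
  m
}

#' @rdname sens_matrix
#' @export
sens_channels <- function(S) setdiff(names(S), "wavelength_nm")

#' @rdname sens_matrix
#' @export
sens_grid <- function(S) as_wavelength_grid(S$wavelength_nm)

#' Synthesize a Gaussian filter-bank sensitivity
#'
#' Stands in for a real camera's measured response curves with a parametric
#' model: channel c responds as
#' `amplitude_c * exp(-(lambda - peak_c)^2 / (2 * width_c^2))`.
#' The defaults emulate a Bayer RGB sensor whose green channel peaks highest,
#' with blue/red slightly lower.
#'
#' @param grid A [wavelength_grid()]; defaults to 410-710 nm in 5 nm steps.
#' @param channel_specs A data frame with columns `channel`, `peak_nm`,
#'   `width_nm`, `amplitude` (one row per channel).
#' @return A `sensor_sensitivity` tibble.
#' @examples
#' S <- synth_sensitivity()
#' sens_channels(S)
#' @export
synth_sensitivity <- function(grid = wavelength_grid(),
                              channel_specs = default_channel_specs()) {
  grid <- as_wavelength_grid(grid)
  required <- c("channel", "peak_nm", "width_nm", "amplitude")
  if (!is.data.frame(channel_specs) || !all(required %in% names(channel_specs)) ||
      nrow(channel_specs) < 1) {
    abort_specdemux(
      "`channel_specs` needs columns channel, peak_nm, width_nm, amplitude",
      "invalid_argument")
  }
  if (any(channel_specs$width_nm <= 0) || any(channel_specs$amplitude <= 0)) {
    abort_specdemux("widths and amplitudes must be > 0", "invalid_argument")
  }
  m <- t(vapply(seq_len(nrow(channel_specs)), function(i) {
    with(channel_specs[i, ],
         amplitude * exp(-(as.double(grid) - peak_nm)^2 / (2 * width_nm^2)))
  }, numeric(length(grid))))
  sensor_sensitivity(grid, m, channels = as.character(channel_specs$channel))
}

#' @rdname synth_sensitivity
#' @export
default_channel_specs <- function() {
  tibble::tibble(
    channel   = c("R", "G", "B"),
    peak_nm   = c(600, 530, 460),
    width_nm  = c(35, 35, 35),
    amplitude = c(0.9, 1.0, 0.8))
}

#' Characterize sensitivity from narrowband sweep responses
#'
#' Emulates the monochromator procedure: narrowband light of unit intensity is
#' swept across the grid and the per-channel sensor response recorded at each
#' wavelength (possibly several repeats). The sensitivity at wavelength
#' `lambda_k` is the per-channel mean response; small negative means (noise
#' artifacts) are clipped to zero, as physical sensitivities are nonnegative.
#'
#' @param responses A data frame with a `wavelength_nm` column plus one column
#'   per channel; one or more rows per grid wavelength.
#' @param grid The [wavelength_grid()] the characterization must cover.
#' @return A `sensor_sensitivity` tibble on `grid`.
#' @export
characterize_from_narrowband <- function(responses, grid) {
  grid <- as_wavelength_grid(grid)
  if (!is.data.frame(responses) || !"wavelength_nm" %in% names(responses)) {
    abort_specdemux("`responses` needs a wavelength_nm column", "invalid_argument")
  }
  channels <- setdiff(names(responses), "wavelength_nm")
  if (length(channels) == 0) {
    abort_specdemux("`responses` has no channel columns", "invalid_argument")
  }
  missing <- setdiff(as.double(grid), unique(responses$wavelength_nm))
  if (length(missing) > 0) {
    abort_specdemux(
      sprintf("characterization incomplete: no responses at %s nm",
              paste(missing, collapse = ", ")),
      "incomplete_characterization", missing_nm = missing)
  }
  means <- responses |>
    dplyr::filter(.data$wavelength_nm %in% as.double(grid)) |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(channels), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$wavelength_nm)
  m <- pmax(t(base::as.matrix(means[channels])), 0)
  sensor_sensitivity(grid, m, channels = channels)
}

#' Read / write a sensitivity CSV
#'
#' The on-disk format is one row per wavelength with header
#' `wavelength_nm,<channel>,...`, plain decimal text. Writing then reading
#' reproduces the matrix to better than 1e-9 element-wise.
#'
#' @param path File path.
#' @return `read_sensitivity_csv()` returns a `sensor_sensitivity` tibble.
#' @export
read_sensitivity_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!"wavelength_nm" %in% names(tbl)) {
    abort_specdemux("sensitivity CSV needs a wavelength_nm column", "validation")
  }
  grid <- as_wavelength_grid(tbl$wavelength_nm)
  channels <- setdiff(names(tbl), "wavelength_nm")
  m <- t(base::as.matrix(tbl[channels]))
  if (any(m < 0)) {
    abort_specdemux("sensitivity CSV contains negative entries", "validation")
  }
  sensor_sensitivity(grid, m, channels = channels)
}

#' @rdname read_sensitivity_csv
#' @param S A `sensor_sensitivity` tibble.
#' @export
write_sensitivity_csv <- function(S, path) {
  readr::write_csv(tibble::as_tibble(unclass_tbl(S)), path)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- class(tibble::tibble())
  x
}

format_wl <- function(wl) {
  vapply(wl, function(x) formatC(x, format = "fg", digits = 15, width = 1),
         character(1))
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.sensor_sensitivity <- function(object, ...) {
  long <- tidyr::pivot_longer(unclass_tbl(object), -"wavelength_nm",
                              names_to = "channel", values_to = "sensitivity")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$sensitivity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "relative sensitivity",
                  colour = NULL)
}
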