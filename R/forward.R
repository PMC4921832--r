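#' Sensor measurements as a tibble
#'
#' One row per measured spectrum: a `spectrum_id` column plus one column per
#' sensor channel, holding the (linear, unquantized) channel intensities
#' produced by the forward model `C = S %*% lambda`.
#'
#' @param x Numeric matrix (rows = measurements, columns = channels) or a
#'   single numeric vector.
#' @param channels Channel labels, one per column.
#' @param ids Optional spectrum identifiers.
#' @return A tibble of class `sensor_measurements`.
#' @export
as_measurements <- function(x, channels, ids = NULL) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || ncol(x) != length(channels)) {
    abort_specdemux("measurements must have one column per channel",
                    "channel_mismatch")
  }
  if (any(!is.finite(x))) {
    abort_specdemux("measurements must be finite", "validation")
  }
  if (is.null(ids)) ids <- seq_len(nrow(x))
  out <- tibble::tibble(spectrum_id = ids)
  for (j in seq_along(channels)) out[[channels[j]]] <- as.double(x[, j])
  class(out) <- c("sensor_measurements", class(tibble::tibble()))
  out
}

#' @rdname as_measurements
#' @param C A `sensor_measurements` tibble.
#' @export
meas_matrix <- function(C) {
  ch <- setdiff(names(C), "spectrum_id")
  m <- base::as.matrix(C[ch])
  rownames(m) <- as.character(C$spectrum_id)
  m
}

#' @rdname as_measurements
#' @export
meas_channels <- function(C) setdiff(names(C), "spectrum_id")

illuminant_values <- function(E, grid) {
  if (is.data.frame(E)) {
    if (!"wavelength_nm" %in% names(E) || ncol(E) < 2) {
      abort_specdemux("illuminant tibble needs wavelength_nm + a value column",
                      "invalid_argument")
    }
    check_same_grid(E$wavelength_nm, grid, "illuminant and spectra")
    E <- E[[setdiff(names(E), "wavelength_nm")[1]]]
  }
  E <- as.double(E)
  if (length(E) != length(grid)) {
    abort_specdemux("illuminant length does not match the grid", "grid_mismatch")
  }
  if (any(!is.finite(E)) || any(E < 0)) {
    abort_specdemux("illuminant power must be finite and >= 0", "validation")
  }
  E
}

#' Scene radiance: reflectance times illuminant
#'
#' Folds the illuminant into the reflectance, `lambda = R * E` element-wise,
#' giving the radiance spectrum arriving at the sensor. Radiance may exceed 1
#' when the illuminant does, so only nonnegativity is enforced on the result.
#'
#' @param sp A `reflectance_spectra` tibble.
#' @param E Illuminant: numeric vector on the same grid, or a tibble with
#'   `wavelength_nm` and a value column.
#' @return A `radiance_spectra` tibble.
#' @export
scene_radiance <- function(sp, E) {
  grid <- spectra_grid(sp)
  Ev <- illuminant_values(E, grid)
  m <- sweep(spectra_matrix(sp), 2, Ev, `*`)
  as_spectra(m, grid, ids = sp$spectrum_id, kind = "radiance")
}

#' Detrend a measured spectrum by the light source
#'
#' Recovers reflectance from a radiance measurement using a near-perfect white
#' reference: dividing the measured spectrum by the spectrum measured off a
#' white target (nominal reflectance `white_reflectance`, default 0.99)
#' cancels the illuminant. The result is clipped to \[0, 1\].
#'
#' @param measured A spectra tibble of measured (radiance) spectra.
#' @param white The spectrum measured off the white reference, same grid:
#'   numeric vector or single-row spectra tibble.
#' @param white_reflectance Nominal reflectance of the white target.
#' @return A `reflectance_spectra` tibble.
#' @export
detrend_by_illuminant <- function(measured, white, white_reflectance = 0.99) {
  grid <- spectra_grid(measured)
  if (is.data.frame(white)) {
    check_same_grid(spectra_grid(white), grid, "white reference and spectra")
    white <- spectra_matrix(white)[1, ]
  }
  white <- as.double(white)
  if (length(white) != length(grid)) {
    abort_specdemux("white reference length does not match the grid",
                    "grid_mismatch")
  }
  bad <- which(white <= 0)
  if (length(bad) > 0) {
    abort_specdemux(
      sprintf("white reference is zero or negative at %s nm",
              paste(as.double(grid)[bad], collapse = ", ")),
      "division_by_zero", wavelength_nm = as.double(grid)[bad])
  }
  m <- sweep(spectra_matrix(measured), 2, white, `/`) * white_reflectance
  as_spectra(pmin(pmax(m, 0), 1), grid, ids = measured$spectrum_id)
}

#' Forward model: spectra to sensor measurements
#'
#' Applies the linear measurement model `C = S %*% lambda` to each spectrum:
#' each channel integrates the incoming spectrum against its sensitivity
#' curve. Vectorized over the rows of `sp`.
#'
#' @param S A `sensor_sensitivity` tibble (p channels on an n-point grid).
#' @param sp A spectra tibble on the same grid (reflectance or radiance), or a
#'   single numeric spectrum.
#' @return A `sensor_measurements` tibble with one row per spectrum.
#' @examples
#' S <- synth_sensitivity()
#' sp <- generate_random_spectra(spectra_gen_config(n_spectra = 3, seed = 1))
#' forward(S, sp)
#' @export
forward <- function(S, sp) {
  grid <- sens_grid(S)
  if (is.numeric(sp) && is.vector(sp)) sp <- as_spectra(sp, grid, kind = "radiance")
  check_same_grid(spectra_grid(sp), grid, "sensitivity and spectra")
  m <- spectra_matrix(sp) %*% t(sens_matrix(S))
  as_measurements(m, sens_channels(S), ids = sp$spectrum_id)
}

#' Add zero-mean Gaussian measurement noise
#'
#' @param C A `sensor_measurements` tibble.
#' @param sigma Noise standard deviation per channel (sensor units), >= 0.
#'   `sigma = 0` returns `C` unchanged.
#' @param seed Optional integer; when given, the draw is deterministic.
#' @return A `sensor_measurements` tibble.
#' @export
add_measurement_noise <- function(C, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma < 0) {
    abort_specdemux("`sigma` must be a single number >= 0", "invalid_argument")
  }
  if (sigma == 0) return(C)
  m <- meas_matrix(C)
  noise <- if (is.null(seed)) {
    matrix(stats::rnorm(length(m), 0, sigma), nrow(m), ncol(m))
  } else {
    withr::with_seed(as.integer(seed),
                     matrix(stats::rnorm(length(m), 0, sigma), nrow(m), ncol(m)))
  }
  as_measurements(m + noise, meas_channels(C), ids = C$spectrum_id)
}

#' Quantize measurements to k-bit levels
#'
#' Optional digitization step: measurements are clamped to `\[0, peak\]` and
#' rounded to `2^bits - 1` uniform levels. The default pipeline keeps
#' measurements continuous.
#'
#' @param C A `sensor_measurements` tibble.
#' @param bits Bit depth (e.g. 8 or 16).
#' @param peak Full-scale value mapped to the top code.
#' @return A `sensor_measurements` tibble.
#' @export
quantize_measurements <- function(C, bits, peak = 1) {
  if (bits < 1 || bits != round(bits)) {
    abort_specdemux("`bits` must be a positive integer", "invalid_argument")
  }
  levels <- 2^bits - 1
  m <- pmin(pmax(meas_matrix(C), 0), peak)
  as_measurements(round(m / peak * levels) / levels * peak,
                  meas_channels(C), ids = C$spectrum_id)
}

#' Render a spectral cube through the sensor
#'
#' Applies the forward model independently at every pixel of a spectral cube,
#' producing the RGB (p-channel) image the sensor would record. Each pixel
#' carries all p channels (post-demosaic view); the Bayer mosaic itself is not
#' modeled.
#'
#' @param S A `sensor_sensitivity` tibble.
#' @param cube A [spectral_cube()] on the same grid.
#' @return A height x width x p numeric array with channel names on the third
#'   dimension.
#' @export
forward_image <- function(S, cube) {
  grid <- sens_grid(S)
  check_same_grid(cube_grid(cube), grid, "sensitivity and cube")
  d <- dim(cube)
  flat <- matrix(as.vector(cube), d[1] * d[2], d[3])
  img <- flat %*% t(sens_matrix(S))
  array(img, dim = c(d[1], d[2], length(sens_channels(S))),
        dimnames = list(NULL, NULL, sens_channels(S)))
}
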