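#' Construct a wavelength grid
#'
#' All spectra, sensitivities and spectral cubes in the package share a
#' uniformly spaced wavelength axis. The default grid spans 410-710 nm in
#' 5 nm steps, giving 61 sample points across the visible band of a
#' consumer RGB sensor.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm); must be reachable from `start_nm`
#'   in whole steps of `step_nm`.
#' @param step_nm Wavelength increment (nm), strictly positive.
#'
#' @return A numeric vector of wavelengths with class `wavelength_grid`.
#' @examples
#' wavelength_grid()            # 61 points, 410-710 nm
#' wavelength_grid(400, 700, 100)
#' @export
wavelength_grid <- function(start_nm = 410, end_nm = 710, step_nm = 5) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || !is.numeric(step_nm) ||
      length(start_nm) != 1 || length(end_nm) != 1 || length(step_nm) != 1 ||
      !is.finite(start_nm) || !is.finite(end_nm) || !is.finite(step_nm)) {
    abort_specdemux("grid bounds and step must be finite scalars",
                    "invalid_argument")
  }
  if (step_nm <= 0) {
    abort_specdemux("`step_nm` must be > 0", "invalid_argument")
  }
  if (end_nm < start_nm) {
    abort_specdemux("`end_nm` must be >= `start_nm`", "invalid_argument")
  }
  n_steps <- (end_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    abort_specdemux(
      sprintf("range %g-%g nm is not a whole number of %g nm steps",
              start_nm, end_nm, step_nm),
      "invalid_grid")
  }
  values <- start_nm + step_nm * seq.int(0L, round(n_steps))
  structure(as.double(values), step_nm = as.double(step_nm),
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d points, %g-%g nm, step %g nm\n",
              length(x), x[1], x[length(x)], grid_step(x)))
  invisible(x)
}

#' Coerce a numeric wavelength vector to a `wavelength_grid`
#'
#' Validates strict increase and uniform spacing.
#'
#' @param x Numeric vector of wavelengths (nm).
#' @return A `wavelength_grid`.
#' @export
as_wavelength_grid <- function(x) {
  if (inherits(x, "wavelength_grid")) return(x)
  x <- as.double(x)
  if (length(x) == 0 || anyNA(x) || any(!is.finite(x))) {
    abort_specdemux("wavelengths must be finite and non-empty", "invalid_grid")
  }
  if (length(x) == 1) {
    return(structure(x, step_nm = NA_real_, class = "wavelength_grid"))
  }
  d <- diff(x)
  if (any(d <= 0)) {
    abort_specdemux("wavelengths must be strictly increasing", "invalid_grid")
  }
  if (max(d) - min(d) > 1e-6 * max(d)) {
    abort_specdemux(
      sprintf("wavelength spacing is not uniform (steps range %g-%g nm)",
              min(d), max(d)),
      "invalid_grid")
  }
  structure(x, step_nm = d[1], class = "wavelength_grid")
}

grid_step <- function(grid) attr(grid, "step_nm")

grids_equal <- function(a, b, tol = 1e-6) {
  length(a) == length(b) && all(abs(as.double(a) - as.double(b)) <= tol)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!grids_equal(a, b)) {
    abort_specdemux(
      sprintf("%s are on different wavelength grids (%d vs %d points)",
              what, length(a), length(b)),
      "grid_mismatch")
  }
  invisible(TRUE)
}

abort_specdemux <- function(message, subclass, ...) {
  rlang::abort(message,
               class = c(paste0("specdemux_", subclass), "specdemux_error"),
               ...)
}
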