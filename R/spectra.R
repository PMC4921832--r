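#' Reflectance spectra as a tibble
#'
#' A spectra object is a tibble with one row per spectrum: a `spectrum_id`
#' column followed by one column per grid wavelength (columns named by the
#' wavelength in nm). Reflectance values are dimensionless fractions in
#' \[0, 1\]; radiance spectra (reflectance times illuminant) relax the upper
#' bound and only require nonnegativity.
#'
#' @param x A numeric matrix (rows = spectra, columns = wavelengths), a single
#'   numeric vector, or a data frame of values.
#' @param grid The [wavelength_grid()] the columns live on.
#' @param ids Optional spectrum identifiers (defaults to `1:n`).
#' @param kind `"reflectance"` (values validated to \[0, 1\]) or `"radiance"`
#'   (values validated to >= 0).
#'
#' @return A tibble of class `reflectance_spectra` (and `radiance_spectra`
#'   for `kind = "radiance"`).
#' @export
as_spectra <- function(x, grid, ids = NULL,
                       kind = c("reflectance", "radiance")) {
  kind <- match.arg(kind)
  grid <- as_wavelength_grid(grid)
  if (is.data.frame(x)) x <- base::as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_specdemux("spectra must be numeric", "invalid_argument")
  }
  if (ncol(x) != length(grid)) {
    abort_specdemux(
      sprintf("spectra have %d values but the grid has %d wavelengths",
              ncol(x), length(grid)),
      "grid_mismatch")
  }
  if (any(!is.finite(x))) {
    abort_specdemux("spectra must be finite", "validation")
  }
  if (any(x < -1e-12) || (kind == "reflectance" && any(x > 1 + 1e-12))) {
    abort_specdemux(
      if (kind == "reflectance") "reflectance values must lie in [0, 1]"
      else "radiance values must be nonnegative",
      "validation")
  }
  if (is.null(ids)) ids <- seq_len(nrow(x))
  out <- tibble::tibble(spectrum_id = ids)
  wl_names <- format_wl(as.double(grid))
  for (j in seq_along(wl_names)) out[[wl_names[j]]] <- as.double(x[, j])
  cls <- c(if (kind == "radiance") "radiance_spectra", "reflectance_spectra",
           class(tibble::tibble()))
  class(out) <- cls
  out
}

new_spectra_raw <- function(m, grid, ids = NULL) {
  if (is.null(ids)) ids <- seq_len(nrow(m))
  out <- tibble::tibble(spectrum_id = ids)
  wl_names <- format_wl(as.double(as_wavelength_grid(grid)))
  for (j in seq_along(wl_names)) out[[wl_names[j]]] <- as.double(m[, j])
  class(out) <- c("reflectance_spectra", class(tibble::tibble()))
  out
}

#' Accessors for spectra tibbles
#'
#' @param sp A `reflectance_spectra` tibble.
#' @return `spectra_matrix()`: a numeric matrix (rows = spectra);
#'   `spectra_grid()`: the shared [wavelength_grid()].
#' @export
spectra_matrix <- function(sp) {
  cols <- setdiff(names(sp), "spectrum_id")
  m <- base::as.matrix(sp[cols])
  rownames(m) <- as.character(sp$spectrum_id)
  m
}

#' @rdname spectra_matrix
#' @export
spectra_grid <- function(sp) {
  as_wavelength_grid(as.double(setdiff(names(sp), "spectrum_id")))
}

#' Write / read a spectra CSV
#'
#' On-disk format: header row of wavelengths in nm, then one row per spectrum
#' (no id column). Round-trips to better than 1e-9.
#'
#' @param sp A `reflectance_spectra` tibble.
#' @param path File path.
#' @param grid Optional grid to validate the file header against.
#' @return `read_spectra_csv()` returns a `reflectance_spectra` tibble; an
#'   empty file yields a zero-row tibble.
#' @export
write_spectra_csv <- function(sp, path) {
  vals <- unclass_tbl(sp)
  vals$spectrum_id <- NULL
  readr::write_csv(vals, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, grid = NULL) {
  if (file.size(path) == 0) {
    if (is.null(grid)) {
      abort_specdemux("empty spectra file and no grid supplied", "invalid_grid")
    }
    return(as_spectra(matrix(numeric(0), 0, length(grid)), grid))
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         name_repair = "minimal")
  file_grid <- tryCatch(as_wavelength_grid(as.double(names(tbl))),
                        error = function(e) {
                          abort_specdemux(
                            "spectra CSV header is not a valid wavelength grid",
                            "grid_mismatch")
                        })
  if (!is.null(grid) && !grids_equal(file_grid, as_wavelength_grid(grid))) {
    abort_specdemux("spectra CSV header does not match the expected grid",
                    "grid_mismatch")
  }
  as_spectra(base::as.matrix(tbl), file_grid)
}

#' @export
autoplot.reflectance_spectra <- function(object, ...) {
  long <- tidyr::pivot_longer(unclass_tbl(object), -"spectrum_id",
                              names_to = "wavelength_nm",
                              values_to = "reflectance")
  long$wavelength_nm <- as.double(long$wavelength_nm)
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$reflectance,
                                     group = .data$spectrum_id,
                                     colour = factor(.data$spectrum_id))) +
    ggplot2::geom_line(show.legend = nrow(object) <= 12) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance", colour = "spectrum")
}
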