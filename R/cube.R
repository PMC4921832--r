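#' Spectral cube: per-pixel reflectance spectra on an image lattice
#'
#' A height x width x n array with the shared [wavelength_grid()] attached;
#' slice `[, , k]` is the band image at the k-th grid wavelength.
#'
#' @param data A numeric height x width x n array, or a matrix (treated as
#'   height x width x 1).
#' @param grid The [wavelength_grid()] of the third dimension.
#' @return An array of class `spectral_cube`.
#' @export
spectral_cube <- function(data, grid) {
  grid <- as_wavelength_grid(grid)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  if (!is.array(data) || length(dim(data)) != 3) {
    abort_specdemux("cube data must be a height x width x n array",
                    "invalid_argument")
  }
  if (dim(data)[3] != length(grid)) {
    abort_specdemux("cube band count does not match the grid", "grid_mismatch")
  }
  if (any(!is.finite(data))) {
    abort_specdemux("cube values must be finite", "validation")
  }
  structure(data, wavelengths = as.double(grid), class = "spectral_cube")
}

#' @rdname spectral_cube
#' @param cube A `spectral_cube`.
#' @export
cube_grid <- function(cube) as_wavelength_grid(attr(cube, "wavelengths"))

#' Flatten a cube to a spectra tibble (one row per pixel)
#'
#' Pixels are ordered column-major (R's native array order); ids are
#' `"row,col"` strings.
#'
#' @param cube A `spectral_cube`.
#' @return A `reflectance_spectra` tibble.
#' @export
cube_to_spectra <- function(cube) {
  d <- dim(cube)
  m <- matrix(as.vector(cube), d[1] * d[2], d[3])
  ids <- paste(rep(seq_len(d[1]), times = d[2]),
               rep(seq_len(d[2]), each = d[1]), sep = ",")
  as_spectra(pmin(pmax(m, 0), 1), cube_grid(cube), ids = ids)
}

#' Extract one band image from a spectral cube
#'
#' @param cube A `spectral_cube`.
#' @param wavelength_nm A wavelength that lies exactly on the cube's grid
#'   (e.g. 490, 550 or 610 on the default grid).
#' @return A height x width numeric matrix.
#' @export
extract_band <- function(cube, wavelength_nm) {
  wl <- as.double(cube_grid(cube))
  k <- which(abs(wl - wavelength_nm) < 1e-9)
  if (length(k) != 1) {
    below <- suppressWarnings(max(wl[wl < wavelength_nm]))
    above <- suppressWarnings(min(wl[wl > wavelength_nm]))
    abort_specdemux(
      sprintf("%g nm is not on the cube grid; nearest grid wavelengths are %s and %s nm",
              wavelength_nm,
              if (is.finite(below)) format(below) else "none",
              if (is.finite(above)) format(above) else "none"),
      "off_grid", nearest_nm = c(below, above))
  }
  cube[, , k]
}

#' Read / write RGB and grayscale images
#'
#' PNG or TIFF, 8- or 16-bit unsigned; pixel codes map linearly to \[0, 1\]
#' (divide by `2^bits - 1`) on read and back on write. Images are treated as
#' linear intensities throughout; no gamma is applied.
#'
#' @param img Numeric array in \[0, 1\]: height x width (grayscale) or
#'   height x width x channels.
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bit depth for writing, 8 or 16.
#' @return `read_rgb_image()` returns a numeric array in \[0, 1\].
#' @export
write_rgb_image <- function(img, path, bits = 8) {
  if (!bits %in% c(8L, 16L)) {
    abort_specdemux("`bits` must be 8 or 16", "invalid_argument")
  }
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path, dpi = NULL)  # writePNG uses 8-bit by default
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = bits)
  } else {
    abort_specdemux(sprintf("unsupported image extension '%s'", ext),
                    "invalid_argument")
  }
  invisible(path)
}

#' @rdname write_rgb_image
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    abort_specdemux(sprintf("unsupported image extension '%s'", ext),
                    "invalid_argument")
  }
}

#' Read / write a spectral cube as multi-band TIFF plus wavelength sidecar
#'
#' Bands are stored as one 32-bit float TIFF page per wavelength in grid
#' order; the sidecar CSV (same path with `.wavelengths.csv` appended) lists
#' the band wavelengths so the grid survives the round trip.
#'
#' @param cube A `spectral_cube`.
#' @param path TIFF file path.
#' @return `read_spectral_cube()` returns a `spectral_cube`.
#' @export
write_spectral_cube <- function(cube, path) {
  d <- dim(cube)
  pages <- lapply(seq_len(d[3]), function(k) cube[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  readr::write_csv(tibble::tibble(wavelength_nm = as.double(cube_grid(cube))),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_spectral_cube
#' @export
read_spectral_cube <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    abort_specdemux("missing wavelength sidecar CSV for cube", "model_format")
  }
  wl <- readr::read_csv(side, show_col_types = FALSE)$wavelength_nm
  if (length(wl) != length(pages)) {
    abort_specdemux("sidecar wavelength count does not match TIFF pages",
                    "grid_mismatch")
  }
  d <- dim(pages[[1]])
  data <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]]
  spectral_cube(data, as_wavelength_grid(wl))
}

sidecar_path <- function(path) paste0(path, ".wavelengths.csv")
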