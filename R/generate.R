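#' Configuration for the random reflectance-spectra generator
#'
#' Spectra are drawn as `baseline + sum of m Gaussian bumps` and clipped to
#' \[0, 1\]: the bump count m is uniform on `modes_min:modes_max`, bump centers
#' are uniform over the grid range, and widths/amplitudes/baseline are uniform
#' in their ranges. The defaults (1-3 bumps, widths 20-80 nm, amplitudes
#' 0.2-1.0, baseline 0-0.2) produce the smooth unimodal/bimodal shapes typical
#' of diffuse reflectance, while covering all wavelengths well across a large
#' population.
#'
#' @param n_spectra Number of spectra to generate (>= 1).
#' @param grid The [wavelength_grid()].
#' @param modes_min,modes_max Bounds on the Gaussian bump count per spectrum.
#' @param width_range_nm Bump standard-deviation range (nm), `c(low, high)`.
#' @param amplitude_range Bump amplitude range, within \[0, 1\].
#' @param baseline_range Flat baseline range, within \[0, 1\].
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A validated list of class `spectra_gen_config`.
#' @export
spectra_gen_config <- function(n_spectra,
                               grid = wavelength_grid(),
                               modes_min = 1, modes_max = 3,
                               width_range_nm = c(20, 80),
                               amplitude_range = c(0.2, 1.0),
                               baseline_range = c(0, 0.2),
                               seed) {
  grid <- as_wavelength_grid(grid)
  bad <- function(msg) abort_specdemux(msg, "validation")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      seed != round(seed)) bad("`seed` must be a single integer")
  if (!is.numeric(n_spectra) || length(n_spectra) != 1 || n_spectra < 1 ||
      n_spectra != round(n_spectra)) bad("`n_spectra` must be an integer >= 1")
  if (modes_min < 1 || modes_max < modes_min) {
    bad("need 1 <= modes_min <= modes_max")
  }
  ordered <- function(r) length(r) == 2 && is.numeric(r) && r[1] <= r[2]
  if (!ordered(width_range_nm) || width_range_nm[1] <= 0) {
    bad("`width_range_nm` must be an ordered positive range")
  }
  if (!ordered(amplitude_range) || amplitude_range[1] < 0 || amplitude_range[2] > 1) {
    bad("`amplitude_range` must be ordered within [0, 1]")
  }
  if (!ordered(baseline_range) || baseline_range[1] < 0 || baseline_range[2] > 1) {
    bad("`baseline_range` must be ordered within [0, 1]")
  }
  structure(list(n_spectra = as.integer(n_spectra), grid = grid,
                 modes_min = as.integer(modes_min),
                 modes_max = as.integer(modes_max),
                 width_range_nm = as.double(width_range_nm),
                 amplitude_range = as.double(amplitude_range),
                 baseline_range = as.double(baseline_range),
                 seed = as.integer(seed)),
            class = "spectra_gen_config")
}

#' Generate a population of random reflectance spectra
#'
#' @param config A [spectra_gen_config()].
#' @return A `reflectance_spectra` tibble with `config$n_spectra` rows.
#' @examples
#' sp <- generate_random_spectra(spectra_gen_config(n_spectra = 5, seed = 42))
#' @export
generate_random_spectra <- function(config) {
  if (!inherits(config, "spectra_gen_config")) {
    abort_specdemux("`config` must come from spectra_gen_config()", "validation")
  }
  wl <- as.double(config$grid)
  n <- length(wl)
  m <- withr::with_seed(config$seed, {
    t(vapply(seq_len(config$n_spectra), function(i) {
      n_modes <- config$modes_min +
        sample.int(config$modes_max - config$modes_min + 1L, 1L) - 1L
      v <- rep(stats::runif(1, config$baseline_range[1],
                            config$baseline_range[2]), n)
      for (j in seq_len(n_modes)) {
        ctr <- stats::runif(1, wl[1], wl[n])
        w <- stats::runif(1, config$width_range_nm[1], config$width_range_nm[2])
        a <- stats::runif(1, config$amplitude_range[1], config$amplitude_range[2])
        v <- v + a * exp(-(wl - ctr)^2 / (2 * w^2))
      }
      pmin(pmax(v, 0), 1)
    }, numeric(n)))
  })
  as_spectra(m, config$grid)
}

#' Generate measurement/spectrum training pairs through the forward model
#'
#' Draws `config$n_spectra` random spectra and pushes each through the forward
#' model of `S`, yielding the (measurement, spectrum) pairs a demultiplexer is
#' trained on.
#'
#' @param S A `sensor_sensitivity` tibble on `config$grid`.
#' @param config A [spectra_gen_config()].
#' @return A list of class `training_pairs` with row-aligned elements
#'   `measurements` (a `sensor_measurements` tibble) and `spectra`
#'   (a `reflectance_spectra` tibble).
#' @export
generate_training_pairs <- function(S, config) {
  check_same_grid(sens_grid(S), config$grid, "sensitivity and generator")
  sp <- generate_random_spectra(config)
  structure(list(measurements = forward(S, sp), spectra = sp),
            class = "training_pairs")
}

#' Build a multi-section test icon
#'
#' A spatial fixture mimicking a printed color test chart: `n_sections`
#' equal-width vertical blocks, each filled with one distinct smooth spectrum
#' (1-2 Gaussian bumps, same generator as the random populations).
#'
#' @param grid The [wavelength_grid()].
#' @param n_sections Number of sections (default 5).
#' @param seed Integer seed.
#' @param section_px Side length of each square section, in pixels.
#' @return A list of class `test_icon` with elements `sections` (a
#'   `reflectance_spectra` tibble whose `spectrum_id` are the section labels)
#'   and `layout` (a character matrix of section labels, `section_px` x
#'   `n_sections * section_px`).
#' @export
make_test_icon <- function(grid = wavelength_grid(), n_sections = 5, seed,
                           section_px = 8) {
  if (n_sections < 1 || n_sections != round(n_sections)) {
    abort_specdemux("`n_sections` must be an integer >= 1", "validation")
  }
  if (section_px < 1 || section_px != round(section_px)) {
    abort_specdemux("`section_px` must be an integer >= 1", "validation")
  }
  cfg <- spectra_gen_config(n_spectra = n_sections, grid = grid,
                            modes_min = 1, modes_max = 2, seed = seed)
  sp <- generate_random_spectra(cfg)
  labels <- paste0("section_", seq_len(n_sections))
  sp$spectrum_id <- labels
  layout <- matrix(rep(labels, each = section_px * section_px),
                   nrow = section_px)
  structure(list(sections = sp, layout = layout,
                 grid = as_wavelength_grid(grid)),
            class = "test_icon")
}

#' Render a test icon as a spectral cube
#'
#' @param icon A [make_test_icon()] result.
#' @return A [spectral_cube()] whose every pixel carries its section's
#'   spectrum.
#' @export
icon_to_cube <- function(icon) {
  m <- spectra_matrix(icon$sections)
  idx <- match(icon$layout, icon$sections$spectrum_id)
  d <- dim(icon$layout)
  data <- array(t(m[idx, , drop = FALSE]), dim = c(length(icon$grid), d[1], d[2]))
  spectral_cube(aperm(data, c(2, 3, 1)), icon$grid)
}

#' Synthetic prior spectra set for the classical Wiener estimator
#'
#' The classical Wiener estimation method (WEM) is trained on a small fixed
#' set of reference patch spectra, in the tradition of color-chart priors.
#' This synthetic stand-in draws 24 broad smooth spectra (1-2 wide bumps,
#' widths 60-150 nm, mild baseline) from the package's generator with a fixed
#' seed, emulating the matte, slowly varying reflectances of chart patches.
#' It is synthetic: no measured chart data is bundled.
#'
#' @param grid The [wavelength_grid()].
#' @param n_spectra Prior set size (default 24 patches).
#' @param seed Fixed seed (default 2024) so the prior is a stable reference.
#' @return A `reflectance_spectra` tibble.
#' @export
wem_prior_spectra <- function(grid = wavelength_grid(), n_spectra = 24,
                              seed = 2024) {
  generate_random_spectra(spectra_gen_config(
    n_spectra = n_spectra, grid = grid, modes_min = 1, modes_max = 2,
    width_range_nm = c(60, 150), amplitude_range = c(0.2, 0.9),
    baseline_range = c(0.05, 0.3), seed = seed))
}
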