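#' Configure the simulation experiment
#'
#' The simulation experiment trains three demultiplexers on the same
#' characterized sensor and scores them on a disjoint population of random
#' test spectra:
#' * `WEM` - Wiener estimation on the small fixed prior of
#'   [wem_prior_spectra()] (the classical baseline);
#' * `DEMUX-WEM` - the same Wiener mathematics trained on the large
#'   generated population pushed through the forward model;
#' * `DEMUX-RFM` - the random-forest demultiplexer trained on the same
#'   forward-model pairs.
#'
#' The full-scale defaults are 10,000 training and 10,000 test spectra with
#' an 8,000-tree forest; reduced-scale runs (e.g. 2,000 / 500 spectra, 300
#' trees) preserve the method ordering at a fraction of the cost.
#'
#' @param S A `sensor_sensitivity` tibble (default: the synthetic Gaussian
#'   filter bank on the 61-point grid).
#' @param n_train,n_test Training/test population sizes.
#' @param train_seed,test_seed Generator seeds; they must differ (leakage
#'   guard) unless `allow_leakage = TRUE`.
#' @param n_trees Total tree count of the forest demultiplexer.
#' @param forest_mode `"joint"` or `"per_wavelength"` (see [train_forest()]).
#' @param forest_seed Seed for forest training (defaults to `train_seed`).
#' @param ridge_eps Wiener ridge; `NULL` for the trace-scaled default.
#' @param n_prior,prior_seed Size and seed of the WEM prior set.
#' @param peak PSNR peak value.
#' @param aggregate PSNR aggregation, `"pooled"` or `"per_spectrum"`.
#' @param allow_leakage Permit equal train/test seeds without warning.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(S = synth_sensitivity(),
                              n_train = 10000, n_test = 10000,
                              train_seed, test_seed,
                              n_trees = 8000,
                              forest_mode = c("joint", "per_wavelength"),
                              forest_seed = NULL,
                              ridge_eps = NULL,
                              n_prior = 24, prior_seed = 2024,
                              peak = 1,
                              aggregate = c("pooled", "per_spectrum"),
                              allow_leakage = FALSE) {
  forest_mode <- match.arg(forest_mode)
  aggregate <- match.arg(aggregate)
  if (missing(train_seed) || missing(test_seed)) {
    abort_specdemux("`train_seed` and `test_seed` must be given explicitly",
                    "validation")
  }
  if (identical(train_seed, test_seed) && !allow_leakage) {
    rlang::warn(paste("training and test generator seeds are equal;",
                      "test spectra will duplicate the training set"),
                class = "specdemux_leakage_warning")
  }
  if (is.null(forest_seed)) forest_seed <- train_seed
  structure(list(S = S, n_train = n_train, n_test = n_test,
                 train_seed = as.integer(train_seed),
                 test_seed = as.integer(test_seed),
                 n_trees = n_trees, forest_mode = forest_mode,
                 forest_seed = as.integer(forest_seed),
                 ridge_eps = ridge_eps,
                 n_prior = n_prior, prior_seed = as.integer(prior_seed),
                 peak = peak, aggregate = aggregate),
            class = "simulation_config")
}

#' Run the simulation experiment
#'
#' Generates disjoint training and test spectra populations, trains WEM,
#' DEMUX-WEM and DEMUX-RFM, scores every method on the same test
#' measurements, and reports per-method PSNR. Fully deterministic for fixed
#' config seeds.
#'
#' @param config A [simulation_config()].
#' @return A `demux_experiment` report: a list with `methods` (tibble of
#'   method, mean PSNR and rank), `per_spectrum` (tibble of per-spectrum
#'   PSNRs), `ranking` (method names, best first) and a config echo.
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_train = 200, n_test = 50, n_trees = 50,
#'                          train_seed = 1, test_seed = 2)
#' rep <- run_simulation_experiment(cfg)
#' rep$methods
#' }
#' @export
run_simulation_experiment <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_specdemux("`config` must come from simulation_config()", "validation")
  }
  S <- config$S
  grid <- sens_grid(S)

  train_cfg <- spectra_gen_config(n_spectra = config$n_train, grid = grid,
                                  seed = config$train_seed)
  pairs <- generate_training_pairs(S, train_cfg)
  test_cfg <- spectra_gen_config(n_spectra = config$n_test, grid = grid,
                                 seed = config$test_seed)
  test_sp <- generate_random_spectra(test_cfg)
  test_C <- forward(S, test_sp)

  models <- list(
    "WEM" = train_wiener(
      wem_prior_spectra(grid, config$n_prior, config$prior_seed),
      S, config$ridge_eps),
    "DEMUX-WEM" = train_wiener(pairs$spectra, S, config$ridge_eps),
    "DEMUX-RFM" = train_forest(pairs, n_trees = config$n_trees,
                               seed = config$forest_seed,
                               mode = config$forest_mode))

  score_methods(models, test_C, test_sp, config, experiment = "simulation")
}

score_methods <- function(models, test_C, test_sp, config, experiment,
                          section_labels = NULL) {
  per <- purrr::map_dfr(names(models), function(nm) {
    pred <- demultiplex(models[[nm]], test_C)
    tibble::tibble(method = nm,
                   spectrum_id = as.character(test_sp$spectrum_id),
                   psnr_db = per_spectrum_psnr(test_sp, pred))
  })
  methods <- purrr::map_dfr(names(models), function(nm) {
    pred <- demultiplex(models[[nm]], test_C)
    tibble::tibble(method = nm,
                   mean_psnr_db = mean_psnr(test_sp, pred, peak = config$peak,
                                            aggregate = config$aggregate))
  })
  methods <- dplyr::arrange(methods, dplyr::desc(.data$mean_psnr_db))
  methods$rank <- seq_len(nrow(methods))
  structure(list(experiment = experiment,
                 methods = methods,
                 per_spectrum = per,
                 ranking = methods$method,
                 config = config_echo(config)),
            class = "demux_experiment")
}

config_echo <- function(config) {
  keep <- config[setdiff(names(config), c("S", "models"))]
  keep <- lapply(keep, function(v) if (is.null(v)) "default" else unclass(v))
  keep
}

#' Configure the icon experiment
#'
#' The spatial counterpart of the simulation experiment: a multi-section test
#' icon is rendered through the forward model into an RGB image, each trained
#' demultiplexer reconstructs a spectral cube from that image, and the mean
#' predicted spectrum of every section is scored against the section's true
#' spectrum.
#'
#' @param S A `sensor_sensitivity` tibble.
#' @param models Named list of trained demultiplexers to evaluate.
#' @param n_sections Number of icon sections (default 5).
#' @param icon_seed Seed for the icon's section spectra.
#' @param section_px Pixel side length of each section.
#' @param noise_sigma Optional measurement noise sd (default 0, noise-free).
#' @param noise_seed Seed for the noise draw.
#' @param peak,aggregate PSNR settings, as in [simulation_config()].
#' @return A validated list of class `icon_config`.
#' @export
icon_config <- function(S, models, n_sections = 5, icon_seed,
                        section_px = 8, noise_sigma = 0, noise_seed = 1,
                        peak = 1, aggregate = c("pooled", "per_spectrum")) {
  aggregate <- match.arg(aggregate)
  if (missing(icon_seed)) {
    abort_specdemux("`icon_seed` must be given explicitly", "validation")
  }
  if (!is.list(models) || length(models) == 0 || is.null(names(models)) ||
      !all(vapply(models, inherits, logical(1), "demultiplexer"))) {
    abort_specdemux("`models` must be a named list of demultiplexers",
                    "validation")
  }
  structure(list(S = S, models = models, n_sections = n_sections,
                 icon_seed = as.integer(icon_seed), section_px = section_px,
                 noise_sigma = noise_sigma, noise_seed = as.integer(noise_seed),
                 peak = peak, aggregate = aggregate),
            class = "icon_config")
}

#' Run the icon experiment
#'
#' @param config An [icon_config()].
#' @return A `demux_experiment` report; `per_spectrum` holds one PSNR entry
#'   per section and method.
#' @export
run_icon_experiment <- function(config) {
  if (!inherits(config, "icon_config")) {
    abort_specdemux("`config` must come from icon_config()", "validation")
  }
  S <- config$S
  grid <- sens_grid(S)
  icon <- make_test_icon(grid, n_sections = config$n_sections,
                         seed = config$icon_seed,
                         section_px = config$section_px)
  cube <- icon_to_cube(icon)
  img <- forward_image(S, cube)
  if (config$noise_sigma > 0) {
    d <- dim(img)
    flat <- as_measurements(matrix(as.vector(img), d[1] * d[2], d[3]),
                            sens_channels(S))
    noisy <- add_measurement_noise(flat, config$noise_sigma, config$noise_seed)
    img <- array(meas_matrix(noisy), dim = d,
                 dimnames = list(NULL, NULL, sens_channels(S)))
  }

  labels <- icon$sections$spectrum_id
  section_mean_spectra <- function(cube_hat) {
    m <- t(vapply(labels, function(lb) {
      idx <- which(icon$layout == lb)
      d <- dim(cube_hat)
      flat <- matrix(as.vector(cube_hat), d[1] * d[2], d[3])
      colMeans(flat[idx, , drop = FALSE])
    }, numeric(length(grid))))
    as_spectra(pmin(pmax(m, 0), 1), grid, ids = labels)
  }

  # mean measurement per section, then per-method reconstruction of the cube
  per <- NULL
  methods <- NULL
  for (nm in names(config$models)) {
    cube_hat <- demultiplex_image(config$models[[nm]], img)
    pred <- section_mean_spectra(cube_hat)
    per <- dplyr::bind_rows(per, tibble::tibble(
      method = nm, spectrum_id = as.character(labels),
      psnr_db = per_spectrum_psnr(icon$sections, pred)))
    methods <- dplyr::bind_rows(methods, tibble::tibble(
      method = nm,
      mean_psnr_db = mean_psnr(icon$sections, pred, peak = config$peak,
                               aggregate = config$aggregate)))
  }
  methods <- dplyr::arrange(methods, dplyr::desc(.data$mean_psnr_db))
  methods$rank <- seq_len(nrow(methods))
  structure(list(experiment = "icon",
                 methods = methods,
                 per_spectrum = per,
                 ranking = methods$method,
                 config = config_echo(config)),
            class = "demux_experiment")
}

#' @export
print.demux_experiment <- function(x, ...) {
  cat(sprintf("<demux_experiment: %s>\n", x$experiment))
  tbl <- x$methods
  for (i in seq_len(nrow(tbl))) {
    cat(sprintf("  %d. %-10s %7.3f dB\n", tbl$rank[i], tbl$method[i],
                tbl$mean_psnr_db[i]))
  }
  invisible(x)
}

#' @export
tidy.demux_experiment <- function(x, ...) x$per_spectrum

#' @export
glance.demux_experiment <- function(x, ...) {
  tibble::tibble(experiment = x$experiment,
                 n_methods = nrow(x$methods),
                 best_method = x$ranking[1],
                 best_psnr_db = x$methods$mean_psnr_db[1])
}

#' @export
autoplot.demux_experiment <- function(object, ...) {
  ggplot2::ggplot(object$methods,
                  ggplot2::aes(stats::reorder(.data$method, .data$mean_psnr_db),
                               .data$mean_psnr_db)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean PSNR (dB)",
                  title = sprintf("%s experiment", object$experiment))
}

#' Write an experiment report as JSON (with a plain-text table alongside)
#'
#' Infinite PSNRs (perfect reconstructions) are encoded as the string
#' `"inf"`. Keys are emitted in a fixed order so identical reports are
#' byte-identical on disk.
#'
#' @param report A `demux_experiment`.
#' @param path Output JSON path.
#' @param text_path Optional path for a plain-text ranking table.
#' @export
write_report_json <- function(report, path, text_path = NULL) {
  enc <- function(v) ifelse(is.finite(v), v, "inf")
  payload <- list(
    experiment = report$experiment,
    ranking = as.list(report$ranking),
    methods = lapply(seq_len(nrow(report$methods)), function(i) {
      list(method = report$methods$method[i],
           mean_psnr_db = enc(report$methods$mean_psnr_db[i]),
           rank = report$methods$rank[i])
    }),
    per_spectrum = lapply(seq_len(nrow(report$per_spectrum)), function(i) {
      list(method = report$per_spectrum$method[i],
           spectrum_id = report$per_spectrum$spectrum_id[i],
           psnr_db = enc(report$per_spectrum$psnr_db[i]))
    }),
    config = report$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(text_path)) {
    lines <- c(sprintf("%s experiment", report$experiment),
               sprintf("%4s  %-12s  %s", "rank", "method", "mean PSNR (dB)"),
               sprintf("%4d  %-12s  %s", report$methods$rank,
                       report$methods$method,
                       formatC(report$methods$mean_psnr_db, digits = 6,
                               format = "f")))
    writeLines(lines, text_path)
  }
  invisible(path)
}
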