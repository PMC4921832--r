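#' Train a Wiener (linear least-squares) demultiplexer
#'
#' Classical spectral-estimation inverse: with training spectra as columns of
#' `A` (n x m) and their simulated measurements `C = S A` (p x m), the
#' estimator is the n x p matrix
#' `W = (A C') (C C' + ridge I)^-1` -
#' the cross-correlation of spectra with measurements times the inverse
#' auto-correlation of measurements (non-centered second moments, the standard
#' convention in Wiener spectral estimation). `W` minimizes the mean squared
#' reconstruction error over the training set, up to the ridge term.
#'
#' Two flavors differ only in the training set: the classical WEM uses the
#' small fixed prior of [wem_prior_spectra()], while the forward-model
#' demultiplexer (DEMUX-WEM) uses a large generated population pushed through
#' the characterized sensor.
#'
#' @param spectra A non-empty `reflectance_spectra` tibble on `S`'s grid.
#' @param S A `sensor_sensitivity` tibble.
#' @param ridge_eps Ridge added to the measurement auto-correlation as
#'   `ridge_eps * I`. `NULL` (default) uses `1e-8 * trace(C C')`; `0` requests
#'   the unregularized solve and errors if the auto-correlation is singular.
#' @return A model of class `wiener_demux`.
#' @examples
#' S <- synth_sensitivity()
#' sp <- generate_random_spectra(spectra_gen_config(n_spectra = 50, seed = 1))
#' w <- train_wiener(sp, S)
#' @export
train_wiener <- function(spectra, S, ridge_eps = NULL) {
  check_same_grid(spectra_grid(spectra), sens_grid(S),
                  "training spectra and sensitivity")
  if (nrow(spectra) == 0) {
    abort_specdemux("training spectra must be non-empty", "validation")
  }
  if (!is.null(ridge_eps) && ridge_eps < 0) {
    abort_specdemux("`ridge_eps` must be >= 0", "invalid_argument")
  }
  A <- t(spectra_matrix(spectra))          # n x m
  Sm <- sens_matrix(S)
  C <- Sm %*% A                            # p x m
  CC <- tcrossprod(C)
  if (is.null(ridge_eps)) ridge_eps <- 1e-8 * sum(diag(CC))
  if (ridge_eps == 0 && rcond(CC) < 1e-12) {
    abort_specdemux(
      "measurement auto-correlation is singular; pass a positive `ridge_eps`",
      "singular_matrix")
  }
  W <- (A %*% t(C)) %*% solve(CC + ridge_eps * diag(nrow(CC)))
  structure(list(W = W, grid = sens_grid(S), channels = sens_channels(S),
                 training_meta = list(n_train = nrow(spectra),
                                      ridge_eps = ridge_eps)),
            class = c("wiener_demux", "demultiplexer"))
}

#' @export
print.wiener_demux <- function(x, ...) {
  cat(sprintf("<wiener_demux> %d x %d map (%s), trained on %d spectra, ridge %g\n",
              nrow(x$W), ncol(x$W), paste(x$channels, collapse = ""),
              x$training_meta$n_train, x$training_meta$ridge_eps))
  invisible(x)
}

#' Export a Wiener demultiplexer matrix as CSV
#'
#' One row per wavelength (`wavelength_nm` column) and one column per channel.
#'
#' @param model A `wiener_demux`.
#' @param path File path.
#' @export
write_wiener_csv <- function(model, path) {
  tbl <- tibble::tibble(wavelength_nm = as.double(model$grid))
  for (j in seq_along(model$channels)) tbl[[model$channels[j]]] <- model$W[, j]
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
tidy.wiener_demux <- function(x, ...) {
  tibble::tibble(
    wavelength_nm = rep(as.double(x$grid), times = length(x$channels)),
    channel = rep(x$channels, each = length(x$grid)),
    weight = as.vector(x$W))
}

#' @importFrom generics glance
#' @export
glance.wiener_demux <- function(x, ...) {
  tibble::tibble(method = "wiener", n_train = x$training_meta$n_train,
                 ridge_eps = x$training_meta$ridge_eps,
                 n_channels = length(x$channels),
                 n_wavelengths = length(x$grid))
}
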