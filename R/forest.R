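#' Train a random-forest demultiplexer
#'
#' Non-linear inverse of the forward model: an ensemble of regression trees
#' mapping a p-channel measurement to the full n-point reflectance spectrum.
#' The default (`mode = "joint"`) grows multi-output trees whose splits
#' maximize the variance reduction summed over all wavelengths, so each leaf
#' predicts a whole (mean) training spectrum - reconstructions stay spectrally
#' coherent. `mode = "per_wavelength"` instead fits one single-output forest
#' per grid wavelength (via ranger), dividing `n_trees` across wavelengths;
#' totals match, but adjacent wavelengths are predicted independently.
#'
#' Hyperparameter defaults follow common random-forest regression practice for
#' tiny feature spaces: unlimited depth, minimum leaf size 1, bootstrap
#' resampling, and all p features considered at every split.
#'
#' @param pairs A [generate_training_pairs()] result, or any list with
#'   row-aligned `measurements` and `spectra` elements.
#' @param n_trees Total tree count across the ensemble (default 8000 at full
#'   scale; reduced-scale experiments use a few hundred).
#' @param seed Integer seed; training is deterministic given it.
#' @param mode `"joint"` (multi-output trees) or `"per_wavelength"`.
#' @param min_node_size Minimum samples per leaf.
#' @param max_depth Maximum tree depth; `0` means unlimited.
#' @param mtry Features tried per split; default all p.
#' @param sample_fraction Bootstrap fraction of the training set per tree.
#' @param replace Bootstrap with replacement?
#' @return A model of class `forest_demux`.
#' @export
train_forest <- function(pairs, n_trees = 8000, seed,
                         mode = c("joint", "per_wavelength"),
                         min_node_size = 1, max_depth = 0, mtry = NULL,
                         sample_fraction = 1, replace = TRUE) {
  mode <- match.arg(mode)
  if (missing(seed) || length(seed) != 1 || seed != round(seed)) {
    abort_specdemux("`seed` must be a single integer", "invalid_argument")
  }
  if (!is.list(pairs) || is.null(pairs$measurements) || is.null(pairs$spectra)) {
    abort_specdemux("`pairs` needs `measurements` and `spectra`", "validation")
  }
  X <- meas_matrix(pairs$measurements)
  Y <- spectra_matrix(pairs$spectra)
  if (nrow(X) == 0 || nrow(X) != nrow(Y)) {
    abort_specdemux("training pairs must be non-empty and row-aligned",
                    "validation")
  }
  if (n_trees < 1 || n_trees != round(n_trees)) {
    abort_specdemux("`n_trees` must be an integer >= 1", "invalid_argument")
  }
  p <- ncol(X)
  n_out <- ncol(Y)
  if (is.null(mtry)) mtry <- p
  grid <- spectra_grid(pairs$spectra)
  channels <- meas_channels(pairs$measurements)

  if (mode == "joint") {
    trees <- cpp_grow_forest(X, Y, as.integer(n_trees), as.integer(mtry),
                             as.integer(min_node_size), as.integer(max_depth),
                             sample_fraction, replace, as.integer(seed))
    fit <- list(trees = trees, Y = Y)
  } else {
    if (n_trees < n_out) {
      abort_specdemux(
        sprintf("per-wavelength mode needs n_trees >= %d (one per wavelength)",
                n_out),
        "invalid_argument")
    }
    per <- rep(n_trees %/% n_out, n_out)
    extra <- n_trees %% n_out
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
    Xdf <- as.data.frame(X)
    fit <- list(forests = lapply(seq_len(n_out), function(k) {
      ranger::ranger(x = Xdf, y = Y[, k], num.trees = per[k],
                     mtry = mtry, min.node.size = min_node_size,
                     replace = replace, sample.fraction = sample_fraction,
                     seed = as.integer(seed) + k, num.threads = 1)
    }))
  }

  structure(list(fit = fit, mode = mode, n_trees = as.integer(n_trees),
                 grid = grid, channels = channels, seed = as.integer(seed),
                 hyperparams = list(min_node_size = min_node_size,
                                    max_depth = max_depth, mtry = mtry,
                                    sample_fraction = sample_fraction,
                                    replace = replace),
                 n_train = nrow(X)),
            class = c("forest_demux", "demultiplexer"))
}

#' @export
print.forest_demux <- function(x, ...) {
  cat(sprintf("<forest_demux> %s, %d trees, trained on %d pairs (%s -> %d wavelengths)\n",
              x$mode, x$n_trees, x$n_train,
              paste(x$channels, collapse = ""), length(x$grid)))
  invisible(x)
}

predict_forest_matrix <- function(model, X) {
  if (model$mode == "joint") {
    cpp_predict_forest(model$fit$trees, X, model$fit$Y)
  } else {
    Xdf <- as.data.frame(X)
    colnames(Xdf) <- model$channels
    vapply(model$fit$forests, function(f) {
      stats::predict(f, Xdf, num.threads = 1)$predictions
    }, numeric(nrow(X)))
  }
}

#' @export
tidy.forest_demux <- function(x, ...) {
  if (x$mode == "joint") {
    tibble::tibble(
      tree = seq_along(x$fit$trees),
      n_nodes = vapply(x$fit$trees, function(t) length(t$var), integer(1)),
      n_leaves = vapply(x$fit$trees, function(t) sum(t$var < 0), integer(1)))
  } else {
    tibble::tibble(
      wavelength_nm = as.double(x$grid),
      n_trees = vapply(x$fit$forests, function(f) f$num.trees, numeric(1)))
  }
}

#' @export
glance.forest_demux <- function(x, ...) {
  tibble::tibble(method = "forest", mode = x$mode, n_trees = x$n_trees,
                 n_train = x$n_train, n_channels = length(x$channels),
                 n_wavelengths = length(x$grid), seed = x$seed)
}
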