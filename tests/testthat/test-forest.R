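toy_pairs <- function(repeats = 20) {
  # 3 distinct spectra with well-separated measurements, each repeated
  g <- tiny_grid(5)
  spectra <- matrix(c(0.9, 0.7, 0.1, 0.1, 0.1,
                      0.1, 0.2, 0.9, 0.2, 0.1,
                      0.1, 0.1, 0.1, 0.7, 0.9), 3, 5, byrow = TRUE)
  meas <- matrix(c(0, 0, 0,
                   5, 5, 5,
                   10, 10, 0), 3, 3, byrow = TRUE)
  idx <- rep(1:3, each = repeats)
  list(measurements = as_measurements(meas[idx, ], c("R", "G", "B")),
       spectra = as_spectra(spectra[idx, ], g),
       truth = spectra, truth_meas = meas, grid = g)
}

test_that("a forest trained on one repeated pair reproduces its target", {
  g <- tiny_grid(4)
  lam <- c(0.2, 0.8, 0.5, 0.1)
  pairs <- list(
    measurements = as_measurements(matrix(rep(c(1, 2, 3), 10), 10, byrow = TRUE),
                                   c("R", "G", "B")),
    spectra = as_spectra(matrix(rep(lam, 10), 10, byrow = TRUE), g))
  for (mode in c("joint", "per_wavelength")) {
    m <- train_forest(pairs, n_trees = 8, seed = 1, mode = mode)
    pred <- demultiplex(m, as_measurements(c(1, 2, 3), c("R", "G", "B")))
    expect_lt(max(abs(spectra_matrix(pred)[1, ] - lam)), 1e-8)
  }
})

test_that("well-separated toy measurements map back to their own spectra", {
  tp <- toy_pairs()
  for (mode in c("joint", "per_wavelength")) {
    m <- train_forest(tp, n_trees = 200, seed = 3, mode = mode)
    pred <- spectra_matrix(demultiplex(
      m, as_measurements(tp$truth_meas, c("R", "G", "B"))))
    expect_lt(max(abs(pred - tp$truth)), 0.01)
  }
})

test_that("the two forest modes agree as independent routes on the toy problem", {
  # joint multi-output trees vs per-wavelength ranger forests: distinct
  # implementations, same target function
  tp <- toy_pairs()
  mj <- train_forest(tp, n_trees = 100, seed = 3, mode = "joint")
  mp <- train_forest(tp, n_trees = 100, seed = 3, mode = "per_wavelength")
  C <- as_measurements(tp$truth_meas, c("R", "G", "B"))
  expect_lt(max(abs(spectra_matrix(demultiplex(mj, C)) -
                    spectra_matrix(demultiplex(mp, C)))), 0.02)
})

test_that("forest training and prediction are deterministic given the seed", {
  tp <- toy_pairs(repeats = 5)
  C <- as_measurements(matrix(c(1, 1, 1, 7, 7, 3), 2, byrow = TRUE),
                       c("R", "G", "B"))
  for (mode in c("joint", "per_wavelength")) {
    m1 <- train_forest(tp, n_trees = 30, seed = 11, mode = mode)
    m2 <- train_forest(tp, n_trees = 30, seed = 11, mode = mode)
    p1 <- demultiplex(m1, C)
    expect_identical(p1, demultiplex(m2, C))
    expect_identical(p1, demultiplex(m1, C))  # repeated calls identical
  }
})

test_that("forest predictions stay within the training range per wavelength", {
  g <- wavelength_grid(450, 600, 10)
  S <- synth_sensitivity(g, tibble::tibble(channel = c("R", "G", "B"),
                                           peak_nm = c(580, 520, 470),
                                           width_nm = 30,
                                           amplitude = c(0.9, 1, 0.8)))
  pairs <- generate_training_pairs(S, spectra_gen_config(
    n_spectra = 100, grid = g, seed = 21))
  m <- train_forest(pairs, n_trees = 50, seed = 22)
  test_C <- forward(S, generate_random_spectra(spectra_gen_config(
    n_spectra = 20, grid = g, seed = 23)))
  pred <- spectra_matrix(demultiplex(m, test_C))
  tr <- spectra_matrix(pairs$spectra)
  for (k in seq_len(ncol(tr))) {
    expect_true(all(pred[, k] >= min(tr[, k]) - 1e-12))
    expect_true(all(pred[, k] <= max(tr[, k]) + 1e-12))
  }
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("forest metadata records the requested ensemble", {
  tp <- toy_pairs(repeats = 3)
  m <- train_forest(tp, n_trees = 40, seed = 2)
  expect_equal(m$n_trees, 40L)
  expect_equal(length(m$fit$trees), 40)
  gl <- generics::glance(m)
  expect_equal(gl$n_trees, 40L)
  expect_equal(gl$mode, "joint")
  # per-wavelength mode divides the total across wavelengths
  mp <- train_forest(tp, n_trees = 12, seed = 2, mode = "per_wavelength")
  expect_equal(sum(generics::tidy(mp)$n_trees), 12)
  # full-scale default requests 8,000 trees
  expect_equal(formals(train_forest)$n_trees, 8000)

  expect_error(train_forest(list(), n_trees = 5, seed = 1),
               class = "specdemux_validation")
  expect_error(train_forest(tp, n_trees = 2, seed = 1, mode = "per_wavelength"),
               class = "specdemux_invalid_argument")
})
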