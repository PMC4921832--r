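test_that("scene radiance is the element-wise reflectance-illuminant product", {
  g <- tiny_grid(2)
  sp <- as_spectra(c(0.2, 0.5), g)
  expect_equal(spectra_matrix(scene_radiance(sp, c(1, 1))),
               spectra_matrix(sp), ignore_attr = TRUE)
  expect_equal(unname(spectra_matrix(scene_radiance(sp, c(2, 4)))[1, ]),
               c(0.4, 2.0))
  zero <- as_spectra(c(0, 0), g)
  expect_equal(unname(spectra_matrix(scene_radiance(zero, c(2, 4)))[1, ]),
               c(0, 0))
  expect_error(scene_radiance(sp, c(1, 2, 3)), class = "specdemux_grid_mismatch")
})

test_that("illuminant detrending inverts the radiance formation", {
  g <- wavelength_grid(450, 550, 10)
  sp <- full_rank_spectra(g, m = 4)
  E <- 0.5 + as.double(g) / 700   # smooth nonuniform illuminant
  rad <- scene_radiance(sp, E)
  rec <- detrend_by_illuminant(rad, white = 0.99 * E)
  expect_lt(max(abs(spectra_matrix(rec) - spectra_matrix(sp))), 1e-9)

  # measuring the white target itself returns its nominal reflectance
  white_rad <- as_spectra(matrix(0.99 * E, 1), g, kind = "radiance")
  rec2 <- detrend_by_illuminant(white_rad, white = 0.99 * E)
  expect_equal(unname(spectra_matrix(rec2)[1, ]), rep(0.99, length(g)))

  bad_white <- replace(E, 3, 0)
  err <- expect_error(detrend_by_illuminant(rad, bad_white),
                      class = "specdemux_division_by_zero")
  expect_match(conditionMessage(err), as.character(as.double(g)[3]))
})

test_that("forward measurements match the explicit summation oracle", {
  g <- wavelength_grid()
  expect_equal(unname(meas_matrix(forward(synth_sensitivity(g),
                                          numeric(61)))[1, ]),
               c(0, 0, 0))

  ones_S <- sensor_sensitivity(g, matrix(1, 1, 61), channels = "sum")
  lam <- withr::with_seed(3, stats::runif(61))
  expect_equal(unname(meas_matrix(forward(ones_S, lam))[1, 1]), sum(lam))

  withr::with_seed(17, {
    S <- random_sensitivity(g)
    lam <- stats::runif(61)
  })
  expect_equal(unname(meas_matrix(forward(S, lam))[1, ]),
               forward_loop_oracle(sens_matrix(S), lam), tolerance = 1e-12)

  sp <- full_rank_spectra(tiny_grid(4), m = 2)
  expect_error(forward(S, sp), class = "specdemux_grid_mismatch")
})

test_that("forward is linear and nonnegative on physical inputs", {
  g <- wavelength_grid(450, 600, 10)
  withr::with_seed(5, {
    S <- random_sensitivity(g)
    l1 <- stats::runif(length(g))
    l2 <- stats::runif(length(g))
    coefs <- matrix(stats::runif(10, -2, 2), 5, 2)
  })
  Sm <- sens_matrix(S)
  for (i in seq_len(nrow(coefs))) {
    a <- coefs[i, 1]; b <- coefs[i, 2]
    lhs <- Sm %*% (a * l1 + b * l2)
    rhs <- a * (Sm %*% l1) + b * (Sm %*% l2)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
  expect_true(all(meas_matrix(forward(S, l1)) >= 0))
})

test_that("measurement noise is seed-deterministic with the requested scale", {
  g <- tiny_grid(5)
  S <- withr::with_seed(2, random_sensitivity(g))
  C <- forward(S, full_rank_spectra(g, m = 2))
  expect_identical(add_measurement_noise(C, 0), C)
  n1 <- add_measurement_noise(C, 0.05, seed = 9)
  n2 <- add_measurement_noise(C, 0.05, seed = 9)
  expect_identical(n1, n2)
  expect_error(add_measurement_noise(C, -1), class = "specdemux_invalid_argument")

  # Monte-Carlo: per-channel sample sd within 5% of sigma
  big <- as_measurements(matrix(0.5, 10000, 3), c("R", "G", "B"))
  noisy <- add_measurement_noise(big, 0.01, seed = 4)
  sds <- apply(meas_matrix(noisy), 2, stats::sd)
  expect_true(all(abs(sds - 0.01) / 0.01 < 0.05))
})

test_that("whole-image rendering equals pixel-wise forward application", {
  g <- wavelength_grid(500, 540, 20)
  S <- withr::with_seed(8, random_sensitivity(g))
  withr::with_seed(12, {
    data <- array(stats::runif(2 * 2 * length(g)), c(2, 2, length(g)))
  })
  cube <- spectral_cube(data, g)
  img <- forward_image(S, cube)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(unname(img[i, j, ]),
                 forward_loop_oracle(sens_matrix(S), data[i, j, ]),
                 tolerance = 1e-12)
  }

  uniform <- spectral_cube(array(rep(data[1, 1, ], each = 4), c(2, 2, length(g))), g)
  uimg <- forward_image(S, uniform)
  expect_equal(max(apply(uimg, 3, function(b) diff(range(b)))), 0)

  zero <- spectral_cube(array(0, c(2, 2, length(g))), g)
  expect_true(all(forward_image(S, zero) == 0))
})

test_that("quantization rounds to the requested bit depth", {
  C <- as_measurements(matrix(c(0.2004, 0.71, 1.4), 1), c("R", "G", "B"))
  q8 <- quantize_measurements(C, 8)
  m <- meas_matrix(q8)
  expect_equal(unname(m[1, ]), round(c(0.2004, 0.71, 1) * 255) / 255)
  expect_error(quantize_measurements(C, 0), class = "specdemux_invalid_argument")
})
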