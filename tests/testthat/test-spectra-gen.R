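test_that("generated spectra respect bounds, length and determinism", {
  cfg <- spectra_gen_config(n_spectra = 50, seed = 42)
  sp <- generate_random_spectra(cfg)
  m <- spectra_matrix(sp)
  expect_equal(dim(m), c(50, 61))
  expect_true(all(m >= 0 & m <= 1))

  expect_identical(generate_random_spectra(cfg), sp)
  other <- generate_random_spectra(spectra_gen_config(n_spectra = 50, seed = 43))
  expect_true(any(spectra_matrix(other) != m))
})

test_that("a large default population represents all wavelengths well", {
  cfg <- spectra_gen_config(n_spectra = 10000, modes_min = 1, modes_max = 3,
                            seed = 42)
  m <- spectra_matrix(generate_random_spectra(cfg))
  mean_curve <- colMeans(m)
  expect_true(all(mean_curve > 0.1 & mean_curve < 0.9))
  # coverage: no dead wavelengths in either direction
  expect_true(all(apply(m, 2, max) > 0.5))
  expect_true(all(apply(m, 2, min) < 0.5))
})

test_that("generator config validation rejects bad ranges", {
  expect_error(spectra_gen_config(n_spectra = 0, seed = 1),
               class = "specdemux_validation")
  expect_error(spectra_gen_config(n_spectra = 5, modes_min = 2, modes_max = 1,
                                  seed = 1),
               class = "specdemux_validation")
  expect_error(spectra_gen_config(n_spectra = 5, amplitude_range = c(0.2, 1.4),
                                  seed = 1),
               class = "specdemux_validation")
  expect_error(spectra_gen_config(n_spectra = 5), class = "specdemux_validation")
})

test_that("training pairs are the generated spectra pushed through the forward model", {
  g <- wavelength_grid()
  S <- synth_sensitivity(g)
  cfg <- spectra_gen_config(n_spectra = 25, seed = 7)
  pairs <- generate_training_pairs(S, cfg)
  expect_equal(nrow(pairs$measurements), 25)
  expect_identical(pairs$spectra, generate_random_spectra(cfg))
  Sm <- sens_matrix(S)
  A <- spectra_matrix(pairs$spectra)
  C <- meas_matrix(pairs$measurements)
  for (i in c(1, 13, 25)) {
    expect_equal(unname(C[i, ]), forward_loop_oracle(Sm, A[i, ]),
                 tolerance = 1e-12)
  }

  # degenerate config: zero-amplitude bumps and zero baseline give zero pairs
  zero_cfg <- spectra_gen_config(n_spectra = 1, amplitude_range = c(0, 0),
                                 baseline_range = c(0, 0), seed = 3)
  zp <- generate_training_pairs(S, zero_cfg)
  expect_true(all(spectra_matrix(zp$spectra) == 0))
  expect_true(all(meas_matrix(zp$measurements) == 0))

  bad_cfg <- spectra_gen_config(n_spectra = 2, grid = tiny_grid(4), seed = 1)
  expect_error(generate_training_pairs(S, bad_cfg),
               class = "specdemux_grid_mismatch")
})

test_that("test icons have labeled uniform sections consistent with the forward model", {
  g <- wavelength_grid()
  S <- synth_sensitivity(g)
  icon <- make_test_icon(g, n_sections = 5, seed = 31, section_px = 4)
  expect_equal(nrow(icon$sections), 5)
  expect_setequal(unique(as.vector(icon$layout)), icon$sections$spectrum_id)
  expect_equal(dim(icon$layout), c(4, 20))

  img <- forward_image(S, icon_to_cube(icon))
  truth_C <- meas_matrix(forward(S, icon$sections))
  d <- dim(img)
  flat <- matrix(as.vector(img), d[1] * d[2], d[3])
  for (i in seq_len(5)) {
    idx <- which(icon$layout == icon$sections$spectrum_id[i])
    section_mean <- colMeans(flat[idx, , drop = FALSE])
    expect_equal(unname(section_mean), unname(truth_C[i, ]), tolerance = 1e-10)
  }

  single <- make_test_icon(g, n_sections = 1, seed = 2, section_px = 3)
  expect_equal(unique(as.vector(single$layout)), "section_1")
  expect_error(make_test_icon(g, n_sections = 0, seed = 1),
               class = "specdemux_validation")
})

test_that("spectra CSV round-trips, rejects mismatched headers, allows empty files", {
  g <- wavelength_grid()
  sp <- generate_random_spectra(spectra_gen_config(n_spectra = 100, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(sp, path)
  back <- read_spectra_csv(path, g)
  expect_lt(max(abs(spectra_matrix(back) - spectra_matrix(sp))), 1e-9)

  expect_error(read_spectra_csv(path, tiny_grid(4)),
               class = "specdemux_grid_mismatch")

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(read_spectra_csv(empty, g)), 0)
})

test_that("the synthetic prior set is small, broad and deterministic", {
  g <- wavelength_grid()
  prior <- wem_prior_spectra(g)
  expect_equal(nrow(prior), 24)
  expect_identical(prior, wem_prior_spectra(g))
  m <- spectra_matrix(prior)
  expect_true(all(m >= 0 & m <= 1))
})
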