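test_that("wavelength grids are uniform, validated, and cover 410-710/5 by default", {
  g <- wavelength_grid()
  expect_length(g, 61)
  expect_equal(as.double(g)[1], 410)
  expect_equal(as.double(g)[61], 710)
  expect_equal(grid_step(g), 5)

  expect_equal(as.double(wavelength_grid(410, 410, 5)), 410)
  expect_equal(as.double(wavelength_grid(400, 700, 100)), c(400, 500, 600, 700))

  expect_error(wavelength_grid(410, 707, 5), class = "specdemux_invalid_grid")
  expect_error(wavelength_grid(410, 710, 0), class = "specdemux_invalid_argument")
  expect_error(wavelength_grid(410, 710, -5), class = "specdemux_invalid_argument")
  expect_error(wavelength_grid(710, 410, 5), class = "specdemux_invalid_argument")
  expect_error(as_wavelength_grid(c(410, 415, 421)), class = "specdemux_invalid_grid")
  expect_error(as_wavelength_grid(c(415, 410)), class = "specdemux_invalid_grid")
})

test_that("synthetic Gaussian sensitivities match the closed-form profile", {
  g <- wavelength_grid()
  S <- synth_sensitivity(g)
  Sm <- sens_matrix(S)
  expect_equal(dim(Sm), c(3, 61))
  specs <- default_channel_specs()
  # direct evaluation of the Gaussian formula as oracle
  for (i in seq_len(nrow(specs))) {
    expected <- specs$amplitude[i] *
      exp(-(as.double(g) - specs$peak_nm[i])^2 / (2 * specs$width_nm[i]^2))
    expect_equal(unname(Sm[specs$channel[i], ]), expected, tolerance = 1e-12)
  }
  # each row unimodal with maximum at the grid point nearest its peak
  for (i in seq_len(nrow(specs))) {
    row <- Sm[specs$channel[i], ]
    k <- which.max(row)
    expect_equal(as.double(g)[k],
                 as.double(g)[which.min(abs(as.double(g) - specs$peak_nm[i]))])
    expect_true(all(diff(row[seq_len(k)]) >= 0))
    expect_true(all(diff(row[k:length(row)]) <= 0))
  }
  # symmetric about an on-grid peak
  S1 <- synth_sensitivity(g, tibble::tibble(channel = "G", peak_nm = 530,
                                            width_nm = 35, amplitude = 1))
  row <- sens_matrix(S1)[1, ]
  expect_equal(unname(row[as.double(g) == 530]), 1.0)
  k <- which(as.double(g) == 530)
  span <- min(k - 1, length(g) - k)
  expect_equal(unname(row[k - seq_len(span)]), unname(row[k + seq_len(span)]),
               tolerance = 1e-12)

  expect_error(
    synth_sensitivity(g, tibble::tibble(channel = "G", peak_nm = 530,
                                        width_nm = 35, amplitude = 0)),
    class = "specdemux_invalid_argument")
  expect_error(
    synth_sensitivity(g, tibble::tibble(channel = "G", peak_nm = 530,
                                        width_nm = -1, amplitude = 1)),
    class = "specdemux_invalid_argument")
})

test_that("narrowband characterization recovers a known sensitivity", {
  g <- wavelength_grid(450, 550, 10)
  withr::with_seed(11, {
    S <- random_sensitivity(g)
  })
  Sm <- sens_matrix(S)
  channels <- sens_channels(S)

  impulse_responses <- function(noise_sd = 0, repeats = 1, seed = 1) {
    withr::with_seed(seed, {
      purrr::map_dfr(seq_along(g), function(k) {
        e_k <- replace(numeric(length(g)), k, 1)
        C <- meas_matrix(forward(S, e_k))[1, ]
        purrr::map_dfr(seq_len(repeats), function(r) {
          obs <- C + stats::rnorm(length(C), 0, noise_sd)
          tibble::tibble(wavelength_nm = as.double(g)[k], !!!as.list(obs))
        })
      })
    })
  }

  # noise-free: exact round trip, S . e_k = column k
  rec <- characterize_from_narrowband(impulse_responses(), g)
  expect_equal(sens_matrix(rec), Sm, tolerance = 1e-15)

  # noisy repeats: recovered columns equal independently computed sample means
  resp <- impulse_responses(noise_sd = 0.02, repeats = 10, seed = 21)
  rec2 <- characterize_from_narrowband(resp, g)
  manual <- sapply(as.double(g), function(wl) {
    block <- resp[resp$wavelength_nm == wl, channels]
    pmax(colMeans(as.matrix(block)), 0)
  })
  expect_equal(unname(sens_matrix(rec2)), unname(manual), tolerance = 1e-12)
  expect_lt(max(abs(sens_matrix(rec2) - Sm)), 0.02 * 5 / sqrt(10))

  # missing wavelength reported by name
  incomplete <- resp[resp$wavelength_nm != 500, ]
  err <- expect_error(characterize_from_narrowband(incomplete, g),
                      class = "specdemux_incomplete_characterization")
  expect_match(conditionMessage(err), "500")
})

test_that("sensitivity CSV round-trips and rejects invalid files", {
  g <- wavelength_grid()
  S <- synth_sensitivity(g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(S, path)
  S2 <- read_sensitivity_csv(path)
  expect_equal(sens_channels(S2), sens_channels(S))
  expect_lt(max(abs(sens_matrix(S2) - sens_matrix(S))), 1e-9)

  bad1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,R", "410,0.5", "415,0.5", "421,0.5"), bad1)
  expect_error(read_sensitivity_csv(bad1), class = "specdemux_invalid_grid")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,R", "410,0.5", "415,-0.1"), bad2)
  expect_error(read_sensitivity_csv(bad2), class = "specdemux_validation")
})
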