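# Shared fixtures built in code; no data files.

tiny_grid <- function(n = 3, start = 500, step = 5) {
  wavelength_grid(start, start + (n - 1) * step, step)
}

# random nonnegative sensitivity with a guaranteed nonzero per row
random_sensitivity <- function(grid, p = 3) {
  m <- matrix(stats::runif(p * length(grid)), p, length(grid))
  sensor_sensitivity(grid, m, channels = paste0("ch", seq_len(p)))
}

# independent brute-force oracle for C = S %*% lambda
forward_loop_oracle <- function(Sm, lambda) {
  out <- numeric(nrow(Sm))
  for (c in seq_len(nrow(Sm))) {
    acc <- 0
    for (k in seq_len(ncol(Sm))) acc <- acc + Sm[c, k] * lambda[k]
    out[c] <- acc
  }
  out
}

# square invertible sensitivity on a p-point grid (p = n exact-inverse limit)
square_sensitivity <- function(p = 3) {
  g <- tiny_grid(p)
  m <- diag(p) + matrix(0.1, p, p)
  sensor_sensitivity(g, m, channels = paste0("ch", seq_len(p)))
}

# small training population with full-rank correlation on a grid
full_rank_spectra <- function(grid, m = 10, seed = 123) {
  withr::with_seed(seed, {
    as_spectra(matrix(stats::runif(m * length(grid)), m), grid)
  })
}
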