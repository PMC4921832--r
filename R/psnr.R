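#' Peak signal-to-noise ratio between spectra
#'
#' `psnr()` computes `10 * log10(peak^2 / MSE)` with the mean squared error
#' taken over wavelengths (and over spectra, when given more than one pair).
#' Identical inputs have zero MSE and return `Inf`, the perfect-reconstruction
#' sentinel. The peak defaults to 1, the full scale of normalized reflectance;
#' absolute dB values depend on this choice.
#'
#' @param truth,pred Numeric vectors/matrices of equal shape, or spectra
#'   tibbles on the same grid.
#' @param peak Peak signal value (> 0).
#' @return Decibels (scalar).
#' @examples
#' psnr(rep(0.5, 61), rep(0.6, 61))  # constant error 0.1 -> 20 dB
#' @export
psnr <- function(truth, pred, peak = 1) {
  truth <- to_values(truth)
  pred <- to_values(pred)
  if (length(truth) != length(pred)) {
    abort_specdemux("`truth` and `pred` have different lengths", "grid_mismatch")
  }
  if (!is.numeric(peak) || length(peak) != 1 || peak <= 0) {
    abort_specdemux("`peak` must be a single number > 0", "invalid_argument")
  }
  mse <- mean((truth - pred)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

to_values <- function(x) {
  if (is.data.frame(x)) x <- spectra_matrix(x)
  as.vector(x)
}

#' Aggregate PSNR over a set of spectra
#'
#' The default pools the squared error over all spectra and wavelengths before
#' taking the ratio (`aggregate = "pooled"`), so a few perfect reconstructions
#' cannot produce an infinite average; the result is infinite only if every
#' reconstruction is exact. `aggregate = "per_spectrum"` instead averages the
#' per-spectrum PSNRs, dropping infinite entries.
#'
#' @param truth,pred Spectra tibbles (or matrices, rows = spectra) of equal
#'   shape.
#' @param peak Peak signal value.
#' @param aggregate `"pooled"` or `"per_spectrum"`.
#' @return Decibels (scalar).
#' @export
mean_psnr <- function(truth, pred, peak = 1,
                      aggregate = c("pooled", "per_spectrum")) {
  aggregate <- match.arg(aggregate)
  tm <- if (is.data.frame(truth)) spectra_matrix(truth) else base::as.matrix(truth)
  pm <- if (is.data.frame(pred)) spectra_matrix(pred) else base::as.matrix(pred)
  if (nrow(tm) == 0) {
    abort_specdemux("need at least one spectrum pair", "validation")
  }
  if (!all(dim(tm) == dim(pm))) {
    abort_specdemux("`truth` and `pred` have different shapes", "grid_mismatch")
  }
  if (aggregate == "pooled") {
    psnr(as.vector(tm), as.vector(pm), peak = peak)
  } else {
    vals <- vapply(seq_len(nrow(tm)),
                   function(i) psnr(tm[i, ], pm[i, ], peak = peak), numeric(1))
    finite <- vals[is.finite(vals)]
    if (length(finite) == 0) Inf else mean(finite)
  }
}

per_spectrum_psnr <- function(truth, pred, peak = 1) {
  tm <- spectra_matrix(truth)
  pm <- spectra_matrix(pred)
  vapply(seq_len(nrow(tm)), function(i) psnr(tm[i, ], pm[i, ], peak = peak),
         numeric(1))
}
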