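#' Smooth Gaussian random field on a grid
#'
#' Spectral synthesis of a stationary, isotropic Gaussian random field:
#' white noise is smoothed with a Gaussian kernel of correlation length
#' `range_cells` via FFT (periodic boundaries), then standardised to mean 0
#' and unit variance. Draws from the current RNG stream, so callers control
#' determinism by seeding.
#'
#' @param nr,nc Grid dimensions.
#' @param range_cells Correlation length in cells (> 0); values below ~0.5
#'   return (standardised) white noise.
#' @return Numeric `nr` x `nc` matrix with mean 0, sd 1.
#' @keywords internal
gaussian_field <- function(nr, nc, range_cells) {
  stopifnot(nr >= 1, nc >= 1, range_cells > 0)
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (range_cells < 0.5) {
    w <- w - mean(w)
    return(w / sd(w))
  }
  # Gaussian kernel on the torus
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  d2 <- outer(dr^2, dc^2, `+`)
  k <- exp(-d2 / (2 * range_cells^2))
  sm <- Re(fft(fft(w) * fft(k), inverse = TRUE)) / (nr * nc)
  sm <- sm - mean(sm)
  sm / sd(sm)
}
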