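#' Band-limited Gaussian noise
#'
#' White Gaussian noise sharply low-pass filtered in the frequency domain
#' (FFT bins above the cutoff zeroed) and standardized to zero mean and unit
#' variance. This is the building block for both the latent signals of the
#' synthetic population generator (0-2.5 Hz, the band relevant to force
#' production) and the independent input noise of the pool simulator
#' (0-50 Hz).
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz).
#' @param ncol Number of independent columns to draw.
#' @return An `n x ncol` matrix, each column zero mean and unit variance.
#' @export
lp_gauss <- function(n, fs, cutoff, ncol = 1) {
  x <- matrix(rnorm(n * ncol), n, ncol)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs <= cutoff | freqs >= fs - cutoff # symmetric spectrum
  apply(x, 2, function(col) {
    xf <- fft(col)
    xf[!keep] <- 0
    y <- Re(fft(xf, inverse = TRUE)) / n
    as.vector(scale(y))
  })
}

# QR-orthogonalize columns, rescaled to unit variance (stays band-limited)
orthogonalize_cols <- function(x) {
  q <- qr.Q(qr(x))
  apply(q, 2, function(col) as.vector(scale(col)))
}

# softmax rows with temperature; low temperature concentrates each row's
# mass on its largest draw
softmax_rows <- function(x, temperature = 0.1) {
  e <- exp((x - apply(x, 1, max)) / temperature)
  e / rowSums(e)
}
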