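#' Truncated Fourier series over wingbeat phase
#'
#' Periodic signals in this package (stroke angle, deviation angle,
#' weight-support profiles) are represented as truncated Fourier series over
#' the wingbeat fraction tau in [0, 1):
#' \deqn{f(\tau) = a_0 + \sum_k a_k \cos(2\pi k\tau) + b_k \sin(2\pi k\tau).}
#'
#' @param a0 mean (zeroth harmonic)
#' @param cos cosine coefficients a_k, k = 1..K
#' @param sin sine coefficients b_k, same length as `cos`
#' @return An object of class `"fourier_series"`.
#' @examples
#' fs <- fourier_series(0, cos = c(1, 0, 0.2))
#' eval_fourier(fs, c(0, 0.25, 0.5))
#' @export
fourier_series <- function(a0 = 0, cos = numeric(0), sin = numeric(0)) {
  k <- max(length(cos), length(sin))
  cos <- c(cos, numeric(k - length(cos)))
  sin <- c(sin, numeric(k - length(sin)))
  if (!all(is.finite(c(a0, cos, sin))))
    stop("Fourier coefficients must be finite")
  structure(list(a0 = a0, cos = cos, sin = sin), class = "fourier_series")
}

#' Evaluate a Fourier series at wingbeat fractions
#'
#' @param fs a [fourier_series()]
#' @param tau wingbeat fractions (any real; the series is 1-periodic)
#' @return Numeric vector of the same length as `tau`.
#' @export
eval_fourier <- function(fs, tau) {
  if (length(tau) == 0) stop("empty phase vector")
  if (!all(is.finite(tau))) stop("non-finite phases")
  out <- rep(fs$a0, length(tau))
  for (k in seq_along(fs$cos)) {
    ang <- 2 * pi * k * tau
    out <- out + fs$cos[k] * cos(ang) + fs$sin[k] * sin(ang)
  }
  out
}

#' Least-squares Fourier fit of sampled periodic data
#'
#' Fits a truncated Fourier series to samples `(phase, y)` by ordinary least
#' squares. Phases need not be uniform, but must cover the period reasonably
#' well for the fit to be identifiable.
#'
#' @param phase wingbeat fractions of the samples
#' @param y sampled values
#' @param n_harmonics truncation order K
#' @return A [fourier_series()].
#' @export
fit_fourier_series <- function(phase, y, n_harmonics = 5) {
  stopifnot(length(phase) == length(y), length(y) > 2 * n_harmonics)
  if (!all(is.finite(phase)) || !all(is.finite(y)))
    stop("non-finite samples")
  X <- matrix(1, length(phase), 1 + 2 * n_harmonics)
  for (k in seq_len(n_harmonics)) {
    X[, 2 * k]     <- cos(2 * pi * k * phase)
    X[, 2 * k + 1] <- sin(2 * pi * k * phase)
  }
  beta <- unname(stats::lm.fit(X, y)$coefficients)
  beta[is.na(beta)] <- 0
  fourier_series(a0 = beta[1],
                 cos = beta[seq(2, by = 2, length.out = n_harmonics)],
                 sin = beta[seq(3, by = 2, length.out = n_harmonics)])
}

#' Spectral (Fourier) differentiation of a periodic series
#'
#' Differentiates a uniformly sampled, exactly periodic series by multiplying
#' its DFT by \eqn{2\pi i k / T}. For bandlimited signals this is accurate to
#' machine precision, with no stencil or endpoint error; the Nyquist bin is
#' zeroed.
#'
#' @param x numeric vector or matrix (columns differentiated independently),
#'   sampled uniformly over exactly one period
#' @param period the period T covered by the samples (s)
#' @return Derivative series, same shape as `x`.
#' @examples
#' t <- seq(0, 1, length.out = 128 + 1)[-129]
#' max(abs(spectral_deriv(sin(2 * pi * t), 1) - 2 * pi * cos(2 * pi * t)))
#' @export
spectral_deriv <- function(x, period) {
  if (is.matrix(x)) return(apply(x, 2, spectral_deriv, period = period))
  n <- length(x)
  if (n < 4) stop("series too short for spectral differentiation")
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0    # zero the Nyquist mode
  w <- 2i * pi * k[seq_len(n)] / period
  Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
}

#' Bandlimit a one-period series by Fourier truncation
#'
#' Zeroes all DFT bins above harmonic `n_harmonics` of a series sampled
#' uniformly over exactly one period. Used to emulate the lowpass filtering
#' of measured force inputs beyond a given wingbeat harmonic.
#'
#' @param x numeric vector or matrix covering exactly one period
#' @param n_harmonics highest harmonic retained
#' @return Truncated series, same shape as `x`.
#' @export
bandlimit_series <- function(x, n_harmonics) {
  if (is.matrix(x)) return(apply(x, 2, bandlimit_series, n_harmonics = n_harmonics))
  n <- length(x)
  stopifnot(n_harmonics >= 0)
  X <- stats::fft(x)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  X[abs(k) > n_harmonics] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Zero-phase periodic Butterworth lowpass
#'
#' Frequency-domain analogue of [lowpass_forces()] for exactly periodic
#' series: each harmonic m is scaled by the forward-backward Butterworth
#' power response \eqn{1 / (1 + (m / m_c)^{2n})}. Unlike a sharp Fourier
#' truncation this rolls off smoothly, so filtered series do not ring
#' (no Gibbs oscillation) and forces still vanish where the underlying
#' signal does — matching the treatment of measured force inputs.
#'
#' @param x numeric vector or matrix covering exactly one period
#' @param cutoff_harmonic half-power harmonic m_c (may be fractional)
#' @param order Butterworth order n (8 matches the measured-force setting)
#' @return Filtered series, same shape as `x`.
#' @export
lowpass_periodic <- function(x, cutoff_harmonic, order = 8) {
  if (is.matrix(x))
    return(apply(x, 2, lowpass_periodic, cutoff_harmonic = cutoff_harmonic,
                 order = order))
  stopifnot(cutoff_harmonic > 0, order >= 1)
  n <- length(x)
  k <- abs(c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)])
  gain <- 1 / (1 + (k / cutoff_harmonic)^(2 * order))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Per-harmonic amplitude (sqrt(a_k^2 + b_k^2)) of a one-period sampled series;
# used by tests and preset validation.
#' Harmonic amplitudes of a one-period series
#' @param x numeric vector sampled uniformly over exactly one period
#' @param n_harmonics number of harmonics to report
#' @return Numeric vector, amplitude of harmonics 1..n_harmonics.
#' @export
harmonic_amplitudes <- function(x, n_harmonics = 6) {
  n <- length(x)
  X <- stats::fft(x) / n
  2 * Mod(X[1 + seq_len(min(n_harmonics, floor(n / 2) - 1))])
}
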