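#' Convert mean-square pressure to sound pressure level and back
#'
#' @param ms mean-square pressure (Pa^2)
#' @param spl sound pressure level (dB)
#' @param p_ref reference pressure (Pa); 20 uPa is the standard airborne
#'   reference
#' @return `ms_to_spl`: dB; `spl_to_ms`: Pa^2. The two are exact inverses.
#' @export
ms_to_spl <- function(ms, p_ref = 20e-6) 10 * log10(ms / p_ref^2)

#' @rdname ms_to_spl
#' @export
spl_to_ms <- function(spl, p_ref = 20e-6) p_ref^2 * 10^(spl / 10)

.trace_pressure <- function(trace) {
  if (inherits(trace, "pressure_trace")) {
    list(p = trace$p, rate = trace$sample_rate, freq = trace$freq)
  } else if (is.numeric(trace)) {
    rate <- attr(trace, "sample_rate")
    if (is.null(rate)) stop("numeric traces need a 'sample_rate' attribute")
    list(p = as.numeric(trace), rate = rate, freq = attr(trace, "freq"))
  } else stop("expected a pressure_trace or numeric vector")
}

#' One-sided SPL spectrum of a pressure trace
#'
#' Computes the one-sided power spectrum (mean-square pressure per bin) and
#' the associated sound pressure level. The default rectangular window over
#' an exact integer number of wingbeat periods is leakage-free for the
#' package's synthetic traces and satisfies Parseval exactly: the per-bin
#' mean-square pressures sum to the time-domain mean square. A Hann window
#' (power-compensated) is available for measured data.
#'
#' @param trace a `"pressure_trace"` or numeric vector with a
#'   `sample_rate` attribute
#' @param window `"rectangular"` or `"hann"`
#' @param p_ref SPL reference pressure (Pa)
#' @return An object of class `"hum_spectrum"`: `frequency` (Hz), `spl`
#'   (dB), `mean_square` (Pa^2 per bin).
#' @export
spl_spectrum <- function(trace, window = c("rectangular", "hann"),
                         p_ref = 20e-6) {
  window <- match.arg(window)
  tr <- .trace_pressure(trace)
  p <- tr$p
  n <- length(p)
  if (!is.null(tr$freq) && n / tr$rate < 2 / tr$freq - 1e-12)
    stop("trace shorter than two wingbeats")
  if (n < 8) stop("trace too short")
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n) else rep(1, n)
  X <- stats::fft(p * w)
  pw <- Mod(X)^2 / n^2 / mean(w^2)
  half <- floor(n / 2)
  ms <- pw[1:(half + 1)]
  if (n %% 2 == 0) ms[2:half] <- 2 * ms[2:half]
  else ms[2:(half + 1)] <- 2 * ms[2:(half + 1)]
  freqs <- (0:half) * tr$rate / n
  all_zero <- all(p == 0)
  structure(list(frequency = freqs,
                 spl = 10 * log10(pmax(ms, .Machine$double.xmin) / p_ref^2),
                 mean_square = ms),
            p_ref = p_ref, window = window, df = tr$rate / n,
            # acoustic (fluctuating) power: the static nearfield offset in
            # the DC bin is not radiated sound
            total_ms = sum(ms) - ms[1],
            fundamental = tr$freq, all_zero = all_zero,
            class = "hum_spectrum")
}

#' @export
print.hum_spectrum <- function(x, ...) {
  cat(sprintf("<hum_spectrum> %d bins, df = %.3g Hz, peak %.1f dB at %.1f Hz\n",
              length(x$frequency), attr(x, "df"),
              max(x$spl), x$frequency[which.max(x$spl)]))
  if (isTRUE(attr(x, "all_zero")))
    cat("  (all-zero trace: levels are at the numerical floor, non-physical)\n")
  invisible(x)
}

#' Per-harmonic band powers and SPL
#'
#' Sums the per-bin mean-square pressure in bands of +/- `half_width` Hz
#' around integer multiples of the wingbeat frequency and reports the band
#' SPL, matching the +/-2.5 Hz band accounting used for hum spectra.
#'
#' @param spectrum a [spl_spectrum()] result
#' @param freq wingbeat frequency f_w (Hz); defaults to the trace fundamental
#' @param n_harmonics number of harmonics (default 10)
#' @param half_width band half-width (Hz)
#' @return A `"harmonic_table"` data frame: `harmonic`, `frequency`,
#'   `band_ms` (Pa^2), `band_spl` (dB), with the trace total mean-square
#'   pressure as attribute `total_ms`.
#' @export
harmonic_bands <- function(spectrum, freq = NULL, n_harmonics = 10,
                           half_width = 2.5) {
  stopifnot(inherits(spectrum, "hum_spectrum"))
  if (is.null(freq)) freq <- attr(spectrum, "fundamental")
  if (is.null(freq)) stop("supply the wingbeat frequency")
  if (freq < 2 * half_width) stop("harmonic bands would overlap (fw too low)")
  if (attr(spectrum, "df") > half_width + 1e-12)
    stop("spectral resolution coarser than the band half-width; use a longer trace")
  p_ref <- attr(spectrum, "p_ref")
  out <- data.frame(harmonic = seq_len(n_harmonics),
                    frequency = freq * seq_len(n_harmonics),
                    band_ms = NA_real_, band_spl = NA_real_)
  for (k in seq_len(n_harmonics)) {
    sel <- abs(spectrum$frequency - k * freq) <= half_width
    out$band_ms[k] <- sum(spectrum$mean_square[sel])
  }
  out$band_spl <- 10 * log10(pmax(out$band_ms, .Machine$double.xmin) / p_ref^2)
  structure(out, total_ms = attr(spectrum, "total_ms"), freq = freq,
            half_width = half_width,
            class = c("harmonic_table", "data.frame"))
}

#' Fraction of total trace power in the first k harmonic bands
#'
#' @param harmonics a [harmonic_bands()] table
#' @param k number of leading harmonics to sum
#' @param total total mean-square pressure of the trace (Pa^2); defaults to
#'   the value carried by the table
#' @return Fraction in `[0, 1]` (Pa^2 ratio).
#' @export
power_concentration <- function(harmonics, k = 4, total = NULL) {
  stopifnot(inherits(harmonics, "harmonic_table"), k >= 1,
            k <= nrow(harmonics))
  if (is.null(total)) total <- attr(harmonics, "total_ms")
  if (is.null(total) || !is.finite(total) || total <= 0)
    stop("zero or unknown total trace power")
  sum(harmonics$band_ms[seq_len(k)]) / total
}

#' Coherent summed-array spectrum
#'
#' Sums pressures sample-wise across an array of observers and computes the
#' spectrum of the sum, emulating summation over all microphones of an
#' array. Traces must share the sampling rate and length; grids offset by an
#' integer number of samples are aligned by periodic rotation.
#'
#' @param traces list of `"pressure_trace"` objects
#' @param ... passed to [spl_spectrum()]
#' @return A `"hum_spectrum"` of the coherent sum.
#' @export
summed_array_spectrum <- function(traces, ...) {
  stopifnot(is.list(traces), length(traces) >= 1)
  ref <- traces[[1]]
  stopifnot(inherits(ref, "pressure_trace"))
  dt <- 1 / ref$sample_rate
  n <- length(ref$p)
  np <- ref$samples_per_period
  psum <- numeric(n)
  for (tr in traces) {
    if (!inherits(tr, "pressure_trace") || length(tr$p) != n ||
        abs(tr$sample_rate - ref$sample_rate) > 1e-9 * ref$sample_rate)
      stop("traces have mismatched time grids")
    off <- (tr$times[1] - ref$times[1]) / dt
    k <- round(off)
    if (abs(off - k) > 1e-6)
      stop("trace grids are not offset by an integer number of samples")
    k <- ((k %% np) + np) %% np
    # value of tr at ref time t is tr's sample k earlier (periodic rotation)
    psum <- psum + tr$p[((seq_len(n) - 1 - k) %% np) + 1]
  }
  out <- psum
  attr(out, "sample_rate") <- ref$sample_rate
  attr(out, "freq") <- ref$freq
  spl_spectrum(out, ...)
}

#' Write a pressure trace as a mono float32 WAV file
#'
#' Renders the hum audible. The RIFF/WAVE container is written directly
#' (IEEE float format 3, mono), with the sample rate rounded to the nearest
#' integer Hz.
#'
#' @param trace a `"pressure_trace"` or numeric vector
#' @param path output file
#' @param sample_rate sampling rate (Hz); taken from the trace if omitted
#' @param scale multiplicative scale applied before writing (pressures are
#'   tiny in Pa; scale up for audibility)
#' @return `path`, invisibly.
#' @export
write_wav <- function(trace, path, sample_rate = NULL, scale = 1) {
  if (inherits(trace, "pressure_trace")) {
    if (is.null(sample_rate)) sample_rate <- trace$sample_rate
    x <- trace$p
  } else x <- as.numeric(trace)
  if (is.null(sample_rate)) stop("sample_rate required")
  sr <- as.integer(round(sample_rate))
  x <- x * scale
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(x) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")        # IEEE float
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 4L, con, size = 4, endian = "little")   # byte rate
  writeBin(4L, con, size = 2, endian = "little")        # block align
  writeBin(32L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}
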