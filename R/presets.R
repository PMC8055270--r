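# Paradigm presets -----------------------------------------------------------
#
# Five groups of flapping fliers, each represented by one well-studied
# paradigm animal: elongated flies (mosquito), compact flies (drosophilid
# fly), lepidoptera (hawkmoth), hummingbirds, and generalist birds
# (parrotlet). The weight-support profile shapes are synthetic stand-ins:
# one half-sine force pulse per half stroke, parameterised by the
# upstroke/downstroke amplitude ratio and the pulse width (fraction of the
# half stroke carrying force), then Fourier-fit. Narrow, nearly symmetric
# pulses (flies) give a dominant second harmonic with substantial content
# up to the sixth; a wide downstroke-only pulse (generalist birds)
# concentrates energy at the first harmonic; intermediate upstroke support
# (hummingbirds, hawkmoths) pairs the first and second harmonics.
# Morphology defaults are literature-scale values for the paradigm animal.

.paradigm <- list(
  elongated_fly = list(
    mass = 2.5e-6, wing_length = 2.94e-3, r3_frac = 0.55, freq = 700,
    stroke_amplitude = 0.7,   # marked shallow stroke of nematoceran flight
    upstroke = 0.90, width = 0.55),
  compact_fly = list(
    mass = 2.0e-6, wing_length = 3.1e-3, r3_frac = 0.55, freq = 200,
    stroke_amplitude = 2.6,
    upstroke = 0.85, width = 0.65),
  lepidoptera = list(
    mass = 1.6e-3, wing_length = 0.05, r3_frac = 0.55, freq = 26,
    stroke_amplitude = 2.0,
    upstroke = 0.55, width = 1),
  hummingbird = list(
    mass = 5.0e-3, wing_length = 0.058, r3_frac = 0.55, freq = 44.2,
    stroke_amplitude = 2.0,
    upstroke = 0.45, width = 1),
  # width 1.25: the downstroke pulse onsets/offsets softly across the
  # reversals, giving the same first-harmonic dominance as a half-sine
  # downstroke-only force trace
  generalist_bird = list(
    mass = 0.030, wing_length = 0.09, r3_frac = 0.58, freq = 20,
    upstroke = 0, width = 1.25,
    stroke_amplitude = 2.0)
)

# Raised-cosine force pulse of width `w` half-strokes centred
# mid-half-stroke: C1-smooth, so its Fourier coefficients decay as 1/k^3 and
# the truncated profile still vanishes at the stroke reversals, as measured
# weight-support traces do.
.force_pulse <- function(tau, centre, w) {
  d <- (tau - centre) %% 1
  d[d > 0.5] <- d[d > 0.5] - 1
  ifelse(abs(d) <= w / 4, 0.5 * (1 + cos(4 * pi * d / w)), 0)
}

.paradigm_profile <- function(g, group) {
  tau <- seq(0, 1, length.out = 513)[-513]
  shape <- .force_pulse(tau, 0.25, g$width) +
    g$upstroke * .force_pulse(tau, 0.75, g$width)
  weight_support_profile(shape, group = group, n_harmonics = 8)
}

#' Paradigm group names
#' @return Character vector of the five registered groups.
#' @export
paradigm_groups <- function() names(.paradigm)

#' Build a paradigm preset
#'
#' Returns the fully populated preset for one of the five paradigm groups:
#' a [flapping_spec()] with the group's default morphology and kinematics
#' (first-harmonic stroke plus a small figure-of-eight deviation with
#' second/third-harmonic content), the group's [weight_support_profile()],
#' and the default constant lift/drag ratio of 2 standing in for the
#' quasi-steady hummingbird polar.
#'
#' @param group one of [paradigm_groups()] (`"hummingbird"`,
#'   `"generalist_bird"`, `"lepidoptera"`, `"compact_fly"`,
#'   `"elongated_fly"`)
#' @param mass,wing_length,freq,stroke_amplitude optional overrides of the
#'   group defaults
#' @return An object of class `"paradigm_preset"`: `group`, `spec`,
#'   `profile`, `lift_drag_ratio`.
#' @examples
#' make_preset("hummingbird")$spec$r3_frac   # 0.55
#' @export
make_preset <- function(group, mass = NULL, wing_length = NULL, freq = NULL,
                        stroke_amplitude = NULL) {
  if (!is.character(group) || length(group) != 1 || !(group %in% names(.paradigm)))
    stop(sprintf("unknown group '%s'; valid groups: %s",
                 as.character(group)[1], paste(names(.paradigm), collapse = ", ")))
  g <- .paradigm[[group]]
  if (!is.null(mass)) g$mass <- mass
  if (!is.null(wing_length)) g$wing_length <- wing_length
  if (!is.null(freq)) g$freq <- freq
  if (!is.null(stroke_amplitude)) g$stroke_amplitude <- stroke_amplitude
  amp <- g$stroke_amplitude
  spec <- flapping_spec(
    mass = g$mass, wing_length = g$wing_length, r3_frac = g$r3_frac,
    freq = g$freq, stroke_amplitude = amp,
    # stroke: dominant first harmonic (downstroke sweeps forward from aft)
    stroke = fourier_series(0, cos = c(-amp / 2, amp * 0.015)),
    # deviation: figure-of-eight with content extending to harmonics 2-3,
    # crossing zero at the stroke reversals (sin-phase second harmonic) so
    # the source velocity direction rotates smoothly through reversal
    deviation = fourier_series(0, cos = c(0.02, 0.03, 0.01),
                               sin = c(0.005, 0.10, 0.005)))
  profile <- .paradigm_profile(g, group)
  structure(list(group = group, spec = spec, profile = profile,
                 lift_drag_ratio = 2),
            class = "paradigm_preset")
}

#' @export
print.paradigm_preset <- function(x, ...) {
  cat(sprintf("<paradigm_preset> %s\n", x$group))
  print(x$spec)
  print(x$profile)
  invisible(x)
}

#' Build a hum model from a preset
#'
#' Convenience wrapper: `hum_model` driven by a preset's spec, profile and
#' lift/drag ratio.
#'
#' @param preset a [make_preset()] result or group name
#' @param ... passed to [hum_model()]
#' @return A [hum_model()].
#' @export
preset_model <- function(preset, ...) {
  if (is.character(preset)) preset <- make_preset(preset)
  stopifnot(inherits(preset, "paradigm_preset"))
  hum_model(preset$spec, weight_support = preset$profile,
            lift_drag_ratio = preset$lift_drag_ratio, ...)
}

# Test signals ----------------------------------------------------------------

#' Deterministic test signals
#'
#' Generates sampled test series with documented analytic properties, for
#' exercising the spectral machinery: a sine (rms = amplitude / sqrt(2)),
#' a two-tone sum, or bandlimited Gaussian noise (deterministic for a fixed
#' seed; flat spectrum up to the cutoff).
#'
#' @param kind `"sine"`, `"two_tone"` or `"bandlimited_noise"`
#' @param sample_rate sampling rate (Hz)
#' @param duration duration (s)
#' @param freq tone frequency (sine), or length-2 vector (two_tone)
#' @param amplitude amplitude (sine), or length-2 vector (two_tone)
#' @param cutoff noise bandwidth (Hz)
#' @param seed RNG seed for the noise kind
#' @return Numeric vector with attributes `sample_rate` and `kind`.
#' @export
make_test_signal <- function(kind = c("sine", "two_tone", "bandlimited_noise"),
                             sample_rate = 4096, duration = 1,
                             freq = 100, amplitude = 1, cutoff = 500,
                             seed = 1) {
  kind <- match.arg(kind)
  stopifnot(sample_rate > 0, duration > 0)
  n <- round(sample_rate * duration)
  t <- (seq_len(n) - 1) / sample_rate
  x <- switch(kind,
    sine = amplitude[1] * sin(2 * pi * freq[1] * t),
    two_tone = {
      if (length(freq) < 2 || length(amplitude) < 2)
        stop("two_tone needs two frequencies and two amplitudes")
      amplitude[1] * sin(2 * pi * freq[1] * t) +
        amplitude[2] * sin(2 * pi * freq[2] * t)
    },
    bandlimited_noise = {
      if (cutoff >= sample_rate / 2) stop("cutoff must be below Nyquist")
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      set.seed(seed)
      w <- stats::rnorm(n)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      X <- stats::fft(w)
      fbin <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)] *
        sample_rate / n
      X[abs(fbin) > cutoff] <- 0
      Re(stats::fft(X, inverse = TRUE)) / n
    })
  attr(x, "sample_rate") <- sample_rate
  attr(x, "kind") <- kind
  x
}
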