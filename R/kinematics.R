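#' Flapping-wing specification
#'
#' Morphology and wingbeat parameterisation of one animal: body mass, wing
#' length R, the effective acoustic source radius R3 (as a fraction of R, the
#' spanwise third moment of area where the net aerodynamic force is placed),
#' flapping frequency, stroke amplitude, and periodic stroke / deviation
#' angle series over the wingbeat fraction tau in [0, 1).
#'
#' Conventions (right-handed, earth-fixed, shoulder pivot at the origin):
#' x anterior, y toward the animal's left, z up. The stroke angle phi is
#' measured in the horizontal stroke plane from the y-axis (mid-stroke
#' abeam), positive sweeping forward; the deviation angle theta is the
#' elevation out of the stroke plane. tau = 0 is the start of downstroke.
#' The stroke series is rescaled on construction so its peak-to-peak range
#' equals `stroke_amplitude` exactly.
#'
#' @param mass body mass m (kg)
#' @param wing_length wing length R (m), measured from the body centre
#' @param r3_frac effective radius fraction R3/R in (0, 1]
#' @param freq flapping frequency f_w (Hz)
#' @param stroke_amplitude peak-to-peak stroke amplitude Phi_o (rad)
#' @param stroke [fourier_series()] for phi(tau); default a pure first
#'   harmonic starting at the aft extreme (downstroke sweeps forward)
#' @param deviation [fourier_series()] for theta(tau); default 0
#' @param downstroke_fraction fraction of the wingbeat spent in downstroke
#' @return An object of class `"flapping_spec"`.
#' @examples
#' spec <- flapping_spec(mass = 5e-3, wing_length = 0.058, freq = 44.2)
#' eval_kinematics(spec, c(0, 0.25, 0.5))
#' @export
flapping_spec <- function(mass, wing_length, r3_frac = 0.55, freq,
                          stroke_amplitude = 2,
                          stroke = NULL, deviation = NULL,
                          downstroke_fraction = 0.5) {
  if (!is.finite(mass) || mass <= 0) stop("mass must be positive")
  if (!is.finite(wing_length) || wing_length <= 0) stop("wing_length must be positive")
  if (!is.finite(r3_frac) || r3_frac <= 0 || r3_frac > 1) stop("r3_frac must lie in (0, 1]")
  if (!is.finite(freq) || freq <= 0) stop("freq must be positive")
  if (!is.finite(stroke_amplitude) || stroke_amplitude <= 0 || stroke_amplitude >= pi)
    stop("stroke_amplitude must lie in (0, pi) radians")
  if (is.null(stroke)) stroke <- fourier_series(0, cos = -stroke_amplitude / 2)
  if (is.null(deviation)) deviation <- fourier_series(0)
  stopifnot(inherits(stroke, "fourier_series"), inherits(deviation, "fourier_series"))
  # enforce the peak-to-peak invariant on a fine grid
  tau <- seq(0, 1, length.out = 4097)[-4097]
  phi <- eval_fourier(stroke, tau)
  ptp <- diff(range(phi))
  if (ptp <= 0) stop("stroke series has zero peak-to-peak range")
  sc <- stroke_amplitude / ptp
  stroke$cos <- stroke$cos * sc
  stroke$sin <- stroke$sin * sc
  structure(list(mass = mass, wing_length = wing_length, r3_frac = r3_frac,
                 freq = freq, stroke_amplitude = stroke_amplitude,
                 stroke = stroke, deviation = deviation,
                 downstroke_fraction = downstroke_fraction),
            class = "flapping_spec")
}

#' @export
print.flapping_spec <- function(x, ...) {
  cat(sprintf(paste0("<flapping_spec> m = %g kg, R = %g m, R3/R = %g, ",
                     "fw = %g Hz, Phi_o = %g rad\n"),
              x$mass, x$wing_length, x$r3_frac, x$freq, x$stroke_amplitude))
  invisible(x)
}

#' Evaluate stroke and deviation angles
#'
#' @param spec a [flapping_spec()]
#' @param phases wingbeat fractions in [0, 1) (values outside are wrapped)
#' @return A data frame with columns `phase`, `stroke` and `deviation` (rad).
#' @export
eval_kinematics <- function(spec, phases) {
  stopifnot(inherits(spec, "flapping_spec"))
  if (length(phases) == 0) stop("empty phase vector")
  if (!all(is.finite(phases))) stop("non-finite phases")
  data.frame(phase = phases,
             stroke = eval_fourier(spec$stroke, phases),
             deviation = eval_fourier(spec$deviation, phases))
}

# Unit direction of the wing source point from (phi, theta) for one side.
# Left wing at phi = theta = 0 points along +y; the right wing is the mirror
# image through the sagittal (x-z) plane.
.wing_direction <- function(phi, theta, side) {
  sgn <- if (side == "left") 1 else -1
  cbind(sin(phi) * cos(theta), sgn * cos(phi) * cos(theta), sin(theta))
}

#' Trajectory of the acoustic source point at radius R3
#'
#' Samples the 3D position, velocity and Mach vector of the equivalent point
#' source located at radius R3 along the wing over one wingbeat. Velocity is
#' obtained by spectral differentiation of the (exactly periodic) position
#' series, so bandlimited kinematics are differentiated to machine precision.
#'
#' @param spec a [flapping_spec()]
#' @param med a [medium()]
#' @param side `"left"` or `"right"`
#' @param samples_per_period samples per wingbeat (>= 64)
#' @param n_periods number of periods to tile into the returned series
#' @return An object of class `"source_trajectory"` with elements `times`,
#'   `phase`, `position`, `velocity`, `mach` (n x 3 matrices), plus the
#'   generating `spec`, `med` and `side`.
#' @export
source_trajectory <- function(spec, med = medium(), side = c("right", "left"),
                              samples_per_period = 1024, n_periods = 1) {
  side <- match.arg(side)
  stopifnot(inherits(spec, "flapping_spec"), inherits(med, "hum_medium"))
  if (samples_per_period < 64) stop("samples_per_period must be >= 64")
  n <- as.integer(samples_per_period)
  tau <- seq_len(n) / n - 1 / n
  kin <- eval_kinematics(spec, tau)
  r3 <- spec$r3_frac * spec$wing_length
  pos <- r3 * .wing_direction(kin$stroke, kin$deviation, side)
  period <- 1 / spec$freq
  vel <- spectral_deriv(pos, period)
  mach <- vel / med$speed_of_sound
  mmag <- sqrt(rowSums(mach^2))
  if (any(mmag >= 1))
    stop(sprintf("source Mach number reaches %.3f >= 1: model invalid", max(mmag)))
  if (n_periods > 1) {
    idx <- rep(seq_len(n), n_periods)
    times <- (seq_len(n * n_periods) - 1) * (period / n)
    traj <- list(times = times, phase = rep(tau, n_periods),
                 position = pos[idx, , drop = FALSE],
                 velocity = vel[idx, , drop = FALSE],
                 mach = mach[idx, , drop = FALSE])
  } else {
    traj <- list(times = (seq_len(n) - 1) * (period / n), phase = tau,
                 position = pos, velocity = vel, mach = mach)
  }
  traj$samples_per_period <- n
  traj$spec <- spec
  traj$med <- med
  traj$side <- side
  class(traj) <- "source_trajectory"
  traj
}

#' @export
print.source_trajectory <- function(x, ...) {
  cat(sprintf("<source_trajectory> %s wing, %d samples/period, peak |M| = %.4f\n",
              x$side, x$samples_per_period, max(sqrt(rowSums(x$mach^2)))))
  invisible(x)
}

# First period of a (possibly tiled) trajectory, as plain matrices.
.traj_period <- function(traj) {
  n <- traj$samples_per_period
  list(position = traj$position[seq_len(n), , drop = FALSE],
       velocity = traj$velocity[seq_len(n), , drop = FALSE],
       mach = traj$mach[seq_len(n), , drop = FALSE])
}
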