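#' Aerodynamic weight-support profile
#'
#' Normalised vertical aerodynamic force (in units of bodyweight) versus
#' wingbeat fraction. Profiles are stored as truncated Fourier series and
#' renormalised on construction so that the wingbeat mean is exactly one
#' bodyweight.
#'
#' @param coefs a [fourier_series()], or a numeric vector of samples over one
#'   period (fitted to `n_harmonics` harmonics)
#' @param group label for the paradigm group this profile represents
#' @param n_harmonics truncation order when fitting from samples
#' @return An object of class `"weight_support_profile"`.
#' @seealso [make_preset()] for the shipped paradigm profiles.
#' @export
weight_support_profile <- function(coefs, group = "custom", n_harmonics = 6) {
  if (is.numeric(coefs)) {
    if (length(coefs) == 0 || all(coefs == 0)) stop("empty or all-zero profile")
    tau <- seq_along(coefs) / length(coefs) - 1 / length(coefs)
    coefs <- fit_fourier_series(tau, coefs, n_harmonics = n_harmonics)
  }
  stopifnot(inherits(coefs, "fourier_series"))
  if (!is.finite(coefs$a0) || coefs$a0 <= 0)
    stop("profile mean must be positive to normalise to bodyweight")
  sc <- 1 / coefs$a0
  coefs$a0 <- 1
  coefs$cos <- coefs$cos * sc
  coefs$sin <- coefs$sin * sc
  structure(list(group = group, coefs = coefs),
            class = "weight_support_profile")
}

#' @export
print.weight_support_profile <- function(x, ...) {
  amp <- round(sqrt(x$coefs$cos^2 + x$coefs$sin^2), 3)
  cat(sprintf("<weight_support_profile> group = %s, harmonic amplitudes (bw): %s\n",
              x$group, paste(amp, collapse = " ")))
  invisible(x)
}

#' Scale a weight-support profile to a body's weight
#'
#' Returns the vertical force series (N) whose wingbeat mean is exactly
#' \eqn{m g}; the profile shape is preserved up to the single scalar factor.
#'
#' @param profile a [weight_support_profile()], or a numeric sample vector
#' @param mass body mass (kg)
#' @param med a [medium()] (supplies g)
#' @param phases wingbeat fractions at which to sample (default 256 uniform)
#' @return Vertical force (N) at `phases`.
#' @export
normalize_weight_support <- function(profile, mass, med = medium(),
                                     phases = seq(0, 1, length.out = 257)[-257]) {
  stopifnot(mass > 0)
  if (is.numeric(profile)) profile <- weight_support_profile(profile)
  stopifnot(inherits(profile, "weight_support_profile"))
  mass * med$gravity * eval_fourier(profile$coefs, phases)
}

#' Drag profile from a lift profile and a lift/drag-ratio rule
#'
#' @param lift lift series L(tau) (N, signed)
#' @param ratio lift/drag ratio rule: a positive scalar, a positive vector
#'   matching `lift`, or a function of wingbeat fraction
#' @param phases wingbeat fractions (required only when `ratio` is a function)
#' @return Drag magnitude series D(tau) = |L| / ratio (N, >= 0).
#' @export
drag_from_lift <- function(lift, ratio = 2, phases = NULL) {
  if (!all(is.finite(lift))) stop("non-finite lift series")
  r <- if (is.function(ratio)) {
    if (is.null(phases)) stop("phases required for a ratio function")
    ratio(phases)
  } else ratio
  if (length(r) != 1 && length(r) != length(lift))
    stop("ratio length does not match lift series")
  if (any(!is.finite(r)) || any(r <= 0)) stop("lift/drag ratio must be positive")
  abs(lift) / r
}

# Unit rows of a matrix; rows with norm below `tol` are replaced by the
# nearest (circularly) row whose norm exceeds tol: the lift/drag direction is
# undefined at stroke reversal and is carried over by continuity.
.safe_unit_rows <- function(v, tol_frac = 1e-6) {
  mag <- sqrt(rowSums(v^2))
  tol <- tol_frac * max(mag)
  bad <- which(mag < tol)
  u <- v / pmax(mag, .Machine$double.xmin)
  if (length(bad) > 0) {
    good <- which(mag >= tol)
    if (length(good) == 0) stop("velocity is identically zero: direction undefined")
    n <- length(mag)
    for (i in bad) {
      d <- pmin(abs(good - i), n - abs(good - i))
      u[i, ] <- u[good[which.min(d)], ]
    }
  }
  u
}

# Lift and drag unit vectors along a trajectory. Drag is antiparallel to the
# source velocity; lift is perpendicular to it in the plane containing the
# spanwise axis normal, with the sign fixed per wing side so that positive
# lift during downstroke points upward on both wings.
.lift_drag_frame <- function(traj) {
  tp <- .traj_period(traj)
  vhat <- .safe_unit_rows(tp$velocity)
  rmag <- sqrt(rowSums(tp$position^2))
  rhat <- tp$position / rmag
  lx <- vhat[, 2] * rhat[, 3] - vhat[, 3] * rhat[, 2]
  ly <- vhat[, 3] * rhat[, 1] - vhat[, 1] * rhat[, 3]
  lz <- vhat[, 1] * rhat[, 2] - vhat[, 2] * rhat[, 1]
  lhat <- cbind(lx, ly, lz)
  if (traj$side == "right") lhat <- -lhat
  lmag <- sqrt(rowSums(lhat^2))
  lhat <- lhat / pmax(lmag, .Machine$double.xmin)
  list(vhat = vhat, lhat = lhat)
}

#' Assemble the 3D per-wing force vector from lift and drag profiles
#'
#' Builds \eqn{F_{wing}(t) = L(\tau)\,\hat l - D(\tau)\,\hat v} on the phase
#' grid of a source trajectory: the drag vector is antiparallel to the source
#' velocity, the lift vector is perpendicular to it (spanwise cross-product
#' construction) and carries the sign of L, so lift flips with stroke
#' direction. At stroke-reversal instants the direction is carried over from
#' the nearest sample.
#'
#' @param traj a [source_trajectory()]
#' @param lift lift series (N, signed), length `samples_per_period`
#' @param drag drag magnitude series (N, >= 0), same length
#' @return An object of class `"wing_force_trajectory"` with elements
#'   `times`, `force` (n x 3, N), `lift`, `drag`, `side`.
#' @export
assemble_force_vector <- function(traj, lift, drag) {
  stopifnot(inherits(traj, "source_trajectory"))
  n <- traj$samples_per_period
  if (length(lift) != n || length(drag) != n)
    stop("lift/drag series must match the trajectory phase grid")
  if (!all(is.finite(lift)) || !all(is.finite(drag)))
    stop("non-finite force inputs")
  if (any(drag < 0)) stop("drag magnitudes must be >= 0")
  fr <- .lift_drag_frame(traj)
  force <- lift * fr$lhat - drag * fr$vhat
  structure(list(times = traj$times[seq_len(n)], force = force,
                 lift = lift, drag = drag, side = traj$side,
                 samples_per_period = n, freq = traj$spec$freq),
            class = "wing_force_trajectory")
}

#' @export
print.wing_force_trajectory <- function(x, ...) {
  cat(sprintf("<wing_force_trajectory> %s wing, %d samples, peak |F| = %.3g N\n",
              x$side, x$samples_per_period, max(sqrt(rowSums(x$force^2)))))
  invisible(x)
}

#' Decompose a net force series into per-wing lift and drag
#'
#' Assumes bilaterally symmetric flight: each wing carries half the net
#' force. The drag is the component of the half-force antiparallel to the
#' source velocity; the lift is the signed component along the lift unit
#' vector of [assemble_force_vector()], making the two operations mutually
#' inverse away from stroke reversals.
#'
#' @param net n x 3 matrix of net aerodynamic force (N)
#' @param traj a [source_trajectory()] for one wing (either side)
#' @return List with numeric `lift` and `drag` series (N) for that wing.
#' @export
decompose_net_force <- function(net, traj) {
  stopifnot(inherits(traj, "source_trajectory"))
  n <- traj$samples_per_period
  if (!is.matrix(net) || nrow(net) != n || ncol(net) != 3)
    stop("net force grid does not match the trajectory grid")
  half <- net / 2
  fr <- .lift_drag_frame(traj)
  drag <- -rowSums(half * fr$vhat)
  lift <- rowSums(half * fr$lhat)
  list(lift = lift, drag = drag)
}

#' Zero-phase Butterworth lowpass filter
#'
#' Applies a digital Butterworth lowpass forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion and exactly unit DC
#' gain (the series mean is removed before filtering and restored after, so
#' constants pass through bit-exactly). Matches the treatment of measured
#' force (8th order, 180 Hz) and kinematics (4th order, 400 Hz) signals.
#'
#' @param x numeric vector or matrix (columns filtered independently)
#' @param order filter order
#' @param cutoff cutoff frequency (Hz), must be below Nyquist
#' @param sample_rate sampling rate of `x` (Hz)
#' @return Filtered series, same shape as `x`.
#' @export
lowpass_forces <- function(x, order = 8, cutoff = 180, sample_rate) {
  stopifnot(order >= 1, cutoff > 0, sample_rate > 0)
  if (cutoff >= sample_rate / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  filt1 <- function(v) {
    mu <- mean(v)
    as.numeric(signal::filtfilt(bf, v - mu)) + mu
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}
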