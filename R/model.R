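#' Two-wing hum model
#'
#' Couples a [flapping_spec()] with per-wing oscillating forces into the
#' object every acoustic routine consumes. Forces can be supplied three ways:
#'
#' * `weight_support`: a [weight_support_profile()] (or a paradigm group name,
#'   see [make_preset()]). Each wing receives half the vertical force target
#'   \eqn{V(\tau) = w(\tau)\,m g / 2}; the signed lift is
#'   \eqn{L = \mathrm{sign}(\hat l_z) V} so lift flips with stroke direction,
#'   and drag follows from `lift_drag_ratio`. The assembled forces are then
#'   rescaled by one global factor so the wingbeat-mean total vertical force
#'   equals \eqn{m g} exactly.
#' * `lift` (+ optional `drag`): explicit per-wing series or functions of
#'   wingbeat fraction, used verbatim on both wings (no rescaling).
#' * neither: defaults to the hummingbird paradigm profile.
#'
#' `harmonic_cutoff` bandlimits the lift and drag input series by Fourier
#' truncation before assembly, emulating lowpass-filtered measured inputs.
#'
#' @param spec a [flapping_spec()]
#' @param med a [medium()]
#' @param weight_support a [weight_support_profile()] or group name
#' @param lift,drag numeric series on the phase grid, or functions of tau
#' @param lift_drag_ratio rule for [drag_from_lift()]
#' @param harmonic_cutoff highest harmonic retained in the force inputs
#'   (NULL = no truncation)
#' @param samples_per_period simulation resolution per wingbeat
#' @return An object of class `"hum_model"` holding the trajectories and
#'   force trajectories of both wings.
#' @examples
#' mod <- hum_model(flapping_spec(5e-3, 0.058, freq = 44.2),
#'                  weight_support = "hummingbird")
#' @export
hum_model <- function(spec, med = medium(), weight_support = NULL,
                      lift = NULL, drag = NULL, lift_drag_ratio = 2,
                      harmonic_cutoff = NULL, samples_per_period = 1024) {
  stopifnot(inherits(spec, "flapping_spec"))
  traj <- list(left = source_trajectory(spec, med, "left", samples_per_period),
               right = source_trajectory(spec, med, "right", samples_per_period))
  n <- samples_per_period
  tau <- traj$left$phase
  as_series <- function(x) {
    if (is.function(x)) x <- x(tau)
    if (length(x) == 1) x <- rep(x, n)
    if (length(x) != n) stop("force series must match the phase grid")
    x
  }
  rescale <- FALSE
  if (is.null(lift)) {
    if (is.null(weight_support)) weight_support <- "hummingbird"
    if (is.character(weight_support))
      weight_support <- make_preset(weight_support)$profile
    stopifnot(inherits(weight_support, "weight_support_profile"))
    vert <- eval_fourier(weight_support$coefs, tau) * spec$mass * med$gravity / 2
    sgn <- sign(.lift_drag_frame(traj$left)$lhat[, 3])
    sgn[sgn == 0] <- 1
    lift <- sgn * vert
    drag <- drag_from_lift(lift, lift_drag_ratio, phases = tau)
    rescale <- TRUE
  } else {
    lift <- as_series(lift)
    drag <- if (is.null(drag)) drag_from_lift(lift, lift_drag_ratio, phases = tau)
            else as_series(drag)
  }
  if (!is.null(harmonic_cutoff)) {
    # smooth zero-phase rolloff just above the cutoff harmonic, mirroring
    # the 8th-order Butterworth at ~180 Hz (= harmonic 4.07) applied to
    # measured forces; a sharp truncation would ring at stroke reversal
    lift <- lowpass_periodic(lift, harmonic_cutoff * 1.02, order = 8)
    drag <- pmax(lowpass_periodic(drag, harmonic_cutoff * 1.02, order = 8), 0)
  }
  forces <- list(left = assemble_force_vector(traj$left, lift, drag),
                 right = assemble_force_vector(traj$right, lift, drag))
  if (rescale) {
    mean_vert <- mean(forces$left$force[, 3] + forces$right$force[, 3])
    if (mean_vert <= 0) stop("assembled forces have non-positive mean vertical component")
    fac <- spec$mass * med$gravity / mean_vert
    for (s in c("left", "right")) {
      forces[[s]]$force <- forces[[s]]$force * fac
      forces[[s]]$lift <- forces[[s]]$lift * fac
      forces[[s]]$drag <- forces[[s]]$drag * fac
    }
  }
  structure(list(spec = spec, med = med, traj = traj, forces = forces,
                 freq = spec$freq, samples_per_period = n,
                 weight_support = if (is.null(weight_support)) NULL
                                  else weight_support$group),
            class = "hum_model")
}

#' @export
print.hum_model <- function(x, ...) {
  cat(sprintf(paste0("<hum_model> fw = %g Hz, %d samples/period, profile = %s\n",
                     "  mean vertical force = %.4g N (m g = %.4g N)\n"),
              x$freq, x$samples_per_period,
              if (is.null(x$weight_support)) "direct lift/drag" else x$weight_support,
              mean(x$forces$left$force[, 3] + x$forces$right$force[, 3]),
              x$spec$mass * x$med$gravity))
  invisible(x)
}

#' Stationary oscillating point force
#'
#' A degenerate single-source "model" whose source point does not move:
#' the classical stationary dipole. Used as the analytic reference case for
#' the propagation solver (closed-form farfield amplitude, directivity and
#' radiated power) and available for constructing arbitrary test sources.
#'
#' @param force_fun function mapping time (s, vector) to an n x 3 force
#'   matrix (N), periodic at `1/freq`
#' @param freq fundamental frequency (Hz)
#' @param position fixed source position (m)
#' @param med a [medium()]
#' @param samples_per_period samples per period
#' @return An object of class `"point_source_set"`.
#' @examples
#' dip <- static_point_force(function(t) cbind(0, 0, sin(2 * pi * 44.2 * t)),
#'                           freq = 44.2)
#' @export
static_point_force <- function(force_fun, freq, position = c(0, 0, 0),
                               med = medium(), samples_per_period = 1024) {
  stopifnot(is.function(force_fun), freq > 0)
  n <- as.integer(samples_per_period)
  t <- (seq_len(n) - 1) / (n * freq)
  force <- force_fun(t)
  if (!is.matrix(force) || nrow(force) != n || ncol(force) != 3)
    stop("force_fun must return an n x 3 matrix")
  if (!all(is.finite(force))) stop("non-finite force values")
  pos <- matrix(rep(position, each = n), n, 3)
  structure(list(sources = list(list(position = pos,
                                     velocity = matrix(0, n, 3),
                                     force = force, label = "static")),
                 freq = freq, med = med, samples_per_period = n),
            class = "point_source_set")
}

# Internal: every acoustic routine works on a list of point sources, each a
# list(position, velocity, force) of one-period n x 3 matrices plus a label.
.hum_sources <- function(model) {
  if (inherits(model, "point_source_set")) return(model$sources)
  if (inherits(model, "hum_model")) {
    lapply(c("left", "right"), function(s) {
      tp <- .traj_period(model$traj[[s]])
      list(position = tp$position, velocity = tp$velocity,
           force = model$forces[[s]]$force, label = s)
    })
  } else stop("expected a hum_model or point_source_set")
}

.hum_freq <- function(model) model$freq
.hum_med <- function(model) model$med
.hum_n <- function(model) model$samples_per_period
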