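#' Observer position
#'
#' @param position 3-vector (m), earth-fixed
#' @param label optional label
#' @return An object of class `"hum_observer"`.
#' @export
observer <- function(position, label = "") {
  position <- as.numeric(position)
  if (length(position) != 3 || !all(is.finite(position)))
    stop("observer position must be a finite 3-vector")
  structure(list(position = position, label = label), class = "hum_observer")
}

.as_observer <- function(x) {
  if (inherits(x, "hum_observer")) x else observer(x)
}

#' Emission-to-arrival time map for a moving source
#'
#' For each emission-time sample of a source trajectory, the time at which
#' the emitted wavefront reaches the observer:
#' \eqn{t_{arr}(t) = t + |x_{obs} - r_s(t)| / a_o}. For subsonic sources the
#' map is strictly increasing, which guarantees a unique emission for every
#' arrival instant.
#'
#' @param traj a [source_trajectory()]
#' @param obs an [observer()] or 3-vector
#' @param med a [medium()] (defaults to the trajectory's)
#' @return Data frame with `time` (emission) and `arrival` (s), one period.
#' @export
emission_map <- function(traj, obs, med = NULL) {
  stopifnot(inherits(traj, "source_trajectory"))
  obs <- .as_observer(obs)
  if (is.null(med)) med <- traj$med
  tp <- .traj_period(traj)
  n <- traj$samples_per_period
  t_emit <- traj$times[seq_len(n)]
  d <- sqrt(colSums((t(tp$position) - obs$position)^2))
  arr <- t_emit + d / med$speed_of_sound
  period <- 1 / traj$spec$freq
  if (any(diff(c(arr, arr[1] + period)) <= 0))
    stop("non-monotone arrival times: line-of-sight Mach number reaches 1")
  data.frame(time = t_emit, arrival = arr)
}

# Core engine: near/farfield pressure contributions of one point source at
# its emission times, one period. Implements both bracketed terms of the
# moving point-force (loading-noise) equation with r, M, Mr evaluated at
# emission time; time derivatives by spectral differentiation of the
# periodic series.
.point_source_pressure <- function(src, obs_pos, freq, med) {
  n <- nrow(src$position)
  period <- 1 / freq
  ao <- med$speed_of_sound
  rvec <- -sweep(src$position, 2, obs_pos)   # x - r_s: source -> observer
  rmag <- sqrt(rowSums(rvec^2))
  if (any(rmag <= 0)) stop("observer coincides with a source sample position")
  M <- src$velocity / ao
  Msq <- rowSums(M * M)
  if (any(Msq >= 1)) stop("source Mach number >= 1")
  Mr <- rowSums(M * rvec) / rmag
  dop <- 1 - Mr
  if (any(abs(dop) < 1e-6)) stop("Doppler factor |1 - Mr| < 1e-6: singular geometry")
  Fd <- spectral_deriv(src$force, period)
  Mr_dot <- spectral_deriv(Mr, period)
  rF <- rowSums(rvec * src$force)
  near <- (1 / (4 * pi * rmag^2 * dop^2)) *
    ((1 / rmag) * ((1 - Msq) / dop) * rF - rowSums(src$force * M))
  far <- (1 / (4 * pi * ao * rmag^2 * dop^2)) *
    (rowSums(rvec * Fd) + (Mr_dot / dop) * rF)
  t_emit <- (seq_len(n) - 1) * period / n
  arr <- t_emit + rmag / ao
  if (any(diff(c(arr, arr[1] + period)) <= 0))
    stop("non-monotone arrival times: line-of-sight Mach number reaches 1")
  list(arrival = arr, near = near, far = far)
}

# Cubic resampling of periodic emission-time channels onto a uniform
# observer-time grid t0 + (0:(n-1)) dt. The channels are tiled over three
# periods so the interpolant is well supported across the period seam.
.resample_periodic <- function(arrival, channels, period, t0, n) {
  dt <- period / n
  a3 <- c(arrival - period, arrival, arrival + period)
  tout <- t0 + (seq_len(n) - 1) * dt
  vapply(channels, function(ch) {
    stats::splinefun(a3, rep(ch, 3), method = "fmm")(tout)
  }, numeric(n))
}

# Shared driver: propagate a list of sources to one observer and build a
# pressure_trace. Sources may carry a side label ("left"/"right") used for
# the per-wing channels.
.propagate <- function(sources, obs, freq, med, n, n_periods) {
  obs <- .as_observer(obs)
  period <- 1 / freq
  dt <- period / n
  parts <- lapply(sources, .point_source_pressure,
                  obs_pos = obs$position, freq = freq, med = med)
  t0 <- ceiling(max(vapply(parts, function(p) p$arrival[1], 0)) / dt - 1e-9) * dt
  near <- far <- numeric(n)
  wings <- list()
  for (i in seq_along(parts)) {
    ch <- .resample_periodic(parts[[i]]$arrival,
                             list(near = parts[[i]]$near, far = parts[[i]]$far),
                             period, t0, n)
    near <- near + ch[, "near"]
    far <- far + ch[, "far"]
    lab <- sources[[i]]$label
    tot <- ch[, "near"] + ch[, "far"]
    wings[[lab]] <- if (is.null(wings[[lab]])) tot else wings[[lab]] + tot
  }
  ntot <- n * n_periods
  idx <- rep(seq_len(n), n_periods)
  structure(list(times = t0 + (seq_len(ntot) - 1) * dt,
                 p = (near + far)[idx],
                 nearfield = near[idx], farfield = far[idx],
                 wings = lapply(wings, function(w) w[idx]),
                 observer = obs, freq = freq, sample_rate = n * freq,
                 samples_per_period = n, n_periods = n_periods, med = med),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(paste0("<pressure_trace> observer (%.3g, %.3g, %.3g) m, ",
                     "%d samples (%d periods), rms = %.3g Pa\n"),
              x$observer$position[1], x$observer$position[2],
              x$observer$position[3], length(x$p), x$n_periods,
              sqrt(mean(x$p^2))))
  invisible(x)
}

#' Acoustic pressure at an observer from the full moving point-force equation
#'
#' Evaluates both bracketed terms of the loading-noise equation for each wing
#' source — the \eqn{1/r^2} nearfield term driven by the force itself and the
#' \eqn{1/r} farfield term driven by the force rate of change and the radial
#' source acceleration — at emission time, maps them through the retarded
#' time (arrival) map, and resamples onto a uniform observer-time grid.
#' Because all model signals are exactly periodic, one emission period is
#' propagated and the steady-state observer period is tiled to the requested
#' analysis length; there is no startup transient.
#'
#' @param model a [hum_model()] or [static_point_force()]
#' @param obs an [observer()] or 3-vector (m)
#' @param n_periods wingbeats in the returned trace (default 18, giving a
#'   spectral resolution of fw/18, finer than the 2.5 Hz band half-width)
#' @return A `"pressure_trace"`: `times`, total `p` (Pa), `nearfield` /
#'   `farfield` channels, per-wing channels in `wings`.
#' @export
pressure_eq1 <- function(model, obs, n_periods = 18) {
  stopifnot(n_periods >= 1)
  .propagate(.hum_sources(model), obs, .hum_freq(model), .hum_med(model),
             .hum_n(model), n_periods)
}

#' Acoustic pressure from the simplified (compact, pivot-referenced) equation
#'
#' The compact-source simplification: the geometry is frozen at the shoulder
#' pivot (r is the constant pivot-to-observer vector), Doppler factors are
#' dropped, and the radial source acceleration is replaced by its magnitude
#' scale \eqn{4\Phi_o R f_w^2 / a_o}:
#' \deqn{p = \frac{r\cdot F}{4\pi|r|^3}
#'       + \frac{1}{4\pi a_o |r|^2}\left(r\cdot\dot F
#'       + \frac{4\Phi_o R f_w^2}{a_o}\, r\cdot F\right).}
#'
#' @inheritParams pressure_eq1
#' @return A `"pressure_trace"` with the same channel layout as
#'   [pressure_eq1()].
#' @export
pressure_eq3 <- function(model, obs, n_periods = 18) {
  stopifnot(inherits(model, "hum_model"), n_periods >= 1)
  obs <- .as_observer(obs)
  spec <- model$spec
  med <- model$med
  n <- model$samples_per_period
  period <- 1 / model$freq
  dt <- period / n
  ao <- med$speed_of_sound
  rvec <- obs$position
  rmag <- sqrt(sum(rvec^2))
  if (rmag <= 0) stop("observer coincides with the pivot")
  kappa <- 4 * spec$stroke_amplitude * spec$wing_length * spec$freq^2 / ao
  delay <- rmag / ao
  t0 <- ceiling(delay / dt - 1e-9) * dt
  shift <- t0 - delay                      # in [0, dt): phase-align like eq1
  near <- far <- numeric(n)
  wings <- list()
  tau_shift <- shift / period
  for (s in c("left", "right")) {
    Fm <- model$forces[[s]]$force
    Fd <- spectral_deriv(Fm, period)
    rF <- as.numeric(Fm %*% rvec)
    rFd <- as.numeric(Fd %*% rvec)
    nr <- rF / (4 * pi * rmag^3)
    fr <- (rFd + kappa * rF) / (4 * pi * ao * rmag^2)
    if (shift > 0) {                       # spectral phase shift to the grid
      nr <- .circular_shift(nr, tau_shift)
      fr <- .circular_shift(fr, tau_shift)
    }
    near <- near + nr
    far <- far + fr
    wings[[s]] <- nr + fr
  }
  ntot <- n * n_periods
  idx <- rep(seq_len(n), n_periods)
  structure(list(times = t0 + (seq_len(ntot) - 1) * dt,
                 p = (near + far)[idx],
                 nearfield = near[idx], farfield = far[idx],
                 wings = lapply(wings, function(w) w[idx]),
                 observer = obs, freq = model$freq, sample_rate = n * model$freq,
                 samples_per_period = n, n_periods = n_periods, med = med),
            class = "pressure_trace")
}

# Shift a one-period series earlier by `frac` of a period via the DFT shift
# theorem (evaluates x(t + frac * T) on the same grid, exactly for
# bandlimited series).
.circular_shift <- function(x, frac) {
  n <- length(x)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  Re(stats::fft(stats::fft(x) * exp(2i * pi * k * frac), inverse = TRUE)) / n
}

#' Distributed spanwise multi-source pressure
#'
#' Replaces the single equivalent point force at R3 by `n_sources` point
#' sources along the span, placed at the centres of equal-width strips of a
#' uniform-chord wing. The per-station force shares are the linear-in-radius
#' weights that conserve both the total instantaneous force and the total
#' aerodynamic torque about the pivot of the single-point R3 model.
#' `n_sources = 1` places the single station at R3 with unit weight and
#' reproduces [pressure_eq1()] exactly.
#'
#' @inheritParams pressure_eq1
#' @param n_sources number of spanwise stations (>= 1)
#' @return A `"pressure_trace"`.
#' @export
pressure_distributed <- function(model, obs, n_sources = 10, n_periods = 18) {
  stopifnot(inherits(model, "hum_model"), n_sources >= 1)
  spec <- model$spec
  R <- spec$wing_length
  r3 <- spec$r3_frac * R
  if (n_sources == 1) {
    radii <- r3; w <- 1
  } else {
    radii <- (seq_len(n_sources) - 0.5) * R / n_sources
    # w_i = a + b r_i with sum(w) = 1 and sum(w r) = r3
    A <- rbind(c(n_sources, sum(radii)), c(sum(radii), sum(radii^2)))
    ab <- solve(A, c(1, r3))
    w <- ab[1] + ab[2] * radii
  }
  if (abs(sum(w) - 1) > 1e-10 || abs(sum(w * radii) - r3) > 1e-10 * r3)
    stop("station weights fail the force/torque conservation constraints")
  sources <- list()
  for (s in c("left", "right")) {
    tp <- .traj_period(model$traj[[s]])
    Fm <- model$forces[[s]]$force
    for (i in seq_len(n_sources)) {
      sc <- radii[i] / r3
      sources[[length(sources) + 1]] <-
        list(position = tp$position * sc, velocity = tp$velocity * sc,
             force = Fm * w[i], label = s)
    }
  }
  .propagate(sources, obs, model$freq, model$med, model$samples_per_period,
             n_periods)
}
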