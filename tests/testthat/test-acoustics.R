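test_that("emission map gives the geometric delay and is invertible", {
  # stationary source 343 m away: constant 1 s delay
  frozen <- flapping_spec(5e-3, 1e-6, freq = 44.2, stroke_amplitude = 1e-6)
  traj <- source_trajectory(frozen, samples_per_period = 64)
  em <- emission_map(traj, c(343, 0, 0))
  expect_equal(em$arrival - em$time, rep(1, 64), tolerance = 1e-7)
  # moving hummingbird source, observer overhead at 0.5 m: delay varies
  # within +/- R3/ao of the mean
  spec <- hb_spec()
  traj <- source_trajectory(spec, side = "left", samples_per_period = 256)
  em <- emission_map(traj, c(0, 0, 0.5))
  delay <- em$arrival - em$time
  r3 <- spec$r3_frac * spec$wing_length
  expect_lt(max(abs(delay - mean(delay))), r3 / 343)
  expect_true(all(diff(em$arrival) > 0))
  # inverse agrees with direct root finding of t_obs - t - |x - r(t)|/ao = 0
  obs <- c(0.4, 0.2, 0.9)
  em <- emission_map(traj, obs)
  pos_fun <- function(t) {
    kin <- eval_kinematics(spec, (t * spec$freq) %% 1)
    r3 * c(sin(kin$stroke) * cos(kin$deviation),
           cos(kin$stroke) * cos(kin$deviation), sin(kin$deviation))
  }
  for (t_obs in c(0.004, 0.012, 0.019)) {
    t_interp <- stats::spline(em$arrival, em$time, xout = t_obs)$y
    f <- function(t) t_obs - t - sqrt(sum((obs - pos_fun(t))^2)) / 343
    t_root <- stats::uniroot(f, c(t_obs - 0.01, t_obs), tol = 1e-13)$root
    expect_lt(abs(t_interp - t_root), 1e-9)
  }
})

test_that("static point forces reproduce the stationary dipole closed forms", {
  # constant force: nearfield term only, p = (r.F)/(4 pi |r|^3)
  const <- static_point_force(function(t) cbind(0, 0, rep(1, length(t))),
                              freq = 44.2, samples_per_period = 64)
  tr <- pressure_eq1(const, c(0, 0, 1), n_periods = 2)
  expect_equal(tr$p, rep(1 / (4 * pi), length(tr$p)), tolerance = 1e-12)
  expect_equal(rms(tr$farfield), 0, tolerance = 1e-15)
  # oscillating force: farfield amplitude 2 pi f F0 cos(theta) / (4 pi ao r)
  f <- 44.2
  dip <- static_dipole(f = f, samples_per_period = 512)
  for (ang in c(0, pi / 3)) {
    obs <- 10 * c(sin(ang), 0, cos(ang))
    tr <- pressure_eq1(dip, obs, n_periods = 2)
    amp <- (max(tr$farfield) - min(tr$farfield)) / 2
    expect_equal(amp, 2 * pi * f * cos(ang) / (4 * pi * 343 * 10),
                 tolerance = 0.01)
  }
})

test_that("trace channels decompose consistently and traces are periodic", {
  mod <- hb_model()
  tr <- pressure_eq1(mod, c(0.5, 0.3, 0.9), n_periods = 3)
  expect_lt(max(abs(tr$nearfield + tr$farfield - tr$p)), 1e-10)
  expect_lt(max(abs(tr$wings$left + tr$wings$right - tr$p)), 1e-10)
  n <- tr$samples_per_period
  expect_identical(tr$p[1:n], tr$p[(n + 1):(2 * n)])
  expect_lt(abs(diff(tr$times[1:2]) * tr$sample_rate - 1), 1e-12)
})

test_that("pressure is linear in the driving forces", {
  spec <- hb_spec()
  l1 <- function(tau) 0.02 * sin(2 * pi * tau)
  l2 <- function(tau) 0.01 * sin(4 * pi * tau)
  obs <- c(0.8, -0.4, 0.6)
  args <- list(spec = spec, lift_drag_ratio = 2, samples_per_period = 256)
  p1 <- pressure_eq1(hum_model(spec, lift = l1, drag = function(t) 0 * t,
                               samples_per_period = 256), obs, 1)$p
  p2 <- pressure_eq1(hum_model(spec, lift = l2, drag = function(t) 0 * t,
                               samples_per_period = 256), obs, 1)$p
  p12 <- pressure_eq1(hum_model(spec, lift = function(t) l1(t) + l2(t),
                                drag = function(t) 0 * t,
                                samples_per_period = 256), obs, 1)$p
  expect_lt(max(abs(p12 - (p1 + p2))), 1e-10)
  # zero force radiates nothing
  p0 <- pressure_eq1(hum_model(spec, lift = function(t) 0 * t,
                               drag = function(t) 0 * t,
                               samples_per_period = 256), obs, 1)$p
  expect_true(all(p0 == 0))
})

test_that("the full equation converges to the stationary dipole as M -> 0", {
  # shrink the stroke so peak |M| <= 1e-3, drive a first-harmonic lift
  spec <- flapping_spec(5e-3, 0.058, freq = 44.2, stroke_amplitude = 0.06)
  mod <- hum_model(spec, lift = function(tau) 0.01 * sin(2 * pi * tau),
                   drag = function(tau) 0 * tau, samples_per_period = 256)
  expect_lt(max(sqrt(rowSums(mod$traj$left$mach^2))), 1e-3)
  tr <- pressure_eq1(mod, c(0, 0, 20), n_periods = 2)
  # both wings' lift is vertical +/-; net vertical force fundamental:
  Fz <- mod$forces$left$force[, 3] + mod$forces$right$force[, 3]
  F1 <- harmonic_amplitudes(Fz, 1)
  pred <- 2 * pi * 44.2 * F1 / (4 * pi * 343 * 20)
  a1 <- harmonic_amplitudes(tr$farfield[1:256] , 1)
  expect_equal(a1, pred, tolerance = 0.01)
})

test_that("nearfield rms decays as 1/r^2 and farfield as 1/r", {
  mod <- hb_model()
  radii <- c(1, 2, 5, 10, 20)
  dir <- c(0.3, 0.25, 0.92) / sqrt(sum(c(0.3, 0.25, 0.92)^2))
  near <- far <- numeric(length(radii))
  for (i in seq_along(radii)) {
    tr <- pressure_eq1(mod, radii[i] * dir, n_periods = 1)
    near[i] <- rms(tr$nearfield - mean(tr$nearfield))
    far[i] <- rms(tr$farfield - mean(tr$farfield))
  }
  fit_near <- stats::coef(stats::lm(log(near) ~ log(radii)))[2]
  fit_far <- stats::coef(stats::lm(log(far) ~ log(radii)))[2]
  expect_equal(unname(fit_near), -2, tolerance = 0.02)
  expect_equal(unname(fit_far), -1, tolerance = 0.02)
})

test_that("the simplified equation tracks the full one at hummingbird scale", {
  # the simplification freezes the geometry at the pivot and drops source-
  # motion (Doppler) mixing, so weak bands near a directivity waist can
  # deviate by a couple of dB while the levels that carry the hum agree
  # closely: dominant two bands to 0.25 dB, all of 1-4 to 2 dB, broadband
  # rms to 5%
  mod <- hb_model()
  for (obs in list(c(0, 0, 1), c(1.5, 1, 2))) {
    s1 <- spl_spectrum(pressure_eq1(mod, obs, 18))
    s3 <- spl_spectrum(pressure_eq3(mod, obs, 18))
    h1 <- harmonic_bands(s1)
    h3 <- harmonic_bands(s3)
    dom <- which(h1$band_spl[1:4] > max(h1$band_spl[1:4]) - 10)
    expect_lt(max(abs(h1$band_spl[dom] - h3$band_spl[dom])), 0.25)
    expect_lt(max(abs(h1$band_spl[1:4] - h3$band_spl[1:4])), 2)
    expect_equal(attr(s3, "total_ms") / attr(s1, "total_ms"), 1,
                 tolerance = 0.05)
  }
})

test_that("one distributed source at R3 is the point model; ten stay within 0.5 dB", {
  mod <- hb_model()
  obs <- c(0.6, 0.4, 0.9)
  tr1 <- pressure_eq1(mod, obs, n_periods = 18)
  trd <- pressure_distributed(mod, obs, n_sources = 1, n_periods = 18)
  expect_identical(tr1$p, trd$p)
  diffs <- c()
  for (o in list(c(0, 0, 1), c(1, 0.5, 1), c(-0.5, 0.8, -0.7))) {
    h1 <- harmonic_bands(spl_spectrum(pressure_eq1(mod, o, 18)))
    h10 <- harmonic_bands(spl_spectrum(pressure_distributed(mod, o, 10, 18)))
    diffs <- c(diffs, abs(h1$band_spl - h10$band_spl))
  }
  expect_lt(stats::median(diffs), 0.5)
})

test_that("forces bandlimited to harmonic 4 still radiate energy above harmonic 4", {
  mod <- hb_model(harmonic_cutoff = 4)
  a <- harmonic_amplitudes(mod$forces$left$lift, 8)
  expect_lt(max(a[6:8]), 1e-3 * max(a))     # inputs really are bandlimited
  tr <- pressure_eq1(mod, c(0.3, 0.4, 0.8), n_periods = 18)
  ht <- harmonic_bands(spl_spectrum(tr))
  high <- sum(ht$band_ms[5:10])
  expect_gt(high, 0)
  expect_gt(high, 1e-8 * sum(ht$band_ms))   # well above numerical noise
})

test_that("compactness and wavelength arithmetic match the printed values", {
  expect_equal(round(wavelength(44.2), 1), 7.8)
  expect_equal(round(wavelength(44.2, 10), 2), 0.78)
  expect_equal(signif(compactness(0.058, 44.2), 1), 0.007)
  expect_equal(compactness(0, 44.2), 0)
})
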