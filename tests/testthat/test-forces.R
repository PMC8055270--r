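test_that("weight-support normalisation rescales to body weight exactly", {
  # constant profile of 2 bodyweights, 5 g animal -> constant 0.04905 N
  out <- normalize_weight_support(rep(2, 64), mass = 5e-3)
  expect_equal(unname(out), rep(0.04905, length(out)), tolerance = 1e-12)
  # half-sine downstroke-only profile: mean is m g to 1e-12 relative
  tau <- (0:255) / 256
  prof <- ifelse(tau < 0.5, sin(2 * pi * tau), 0)
  out <- normalize_weight_support(prof, mass = 0.03,
                                  phases = seq(0, 1, length.out = 4097)[-4097])
  expect_lt(abs(mean(out) - 0.03 * 9.81) / (0.03 * 9.81), 1e-12)
  expect_error(normalize_weight_support(rep(0, 16), 0.01), "zero")
  expect_error(weight_support_profile(fourier_series(-1)), "positive")
})

test_that("hummingbird paradigm profile keeps harmonics 1 and 2 both strong", {
  out <- normalize_weight_support(make_preset("hummingbird")$profile, 5e-3,
                                  phases = (0:255) / 256)
  a <- harmonic_amplitudes(out, 6)
  expect_gt(a[1], 0.5 * a[2])
  expect_gt(a[2], 0.5 * a[1])
  expect_gt(min(a[1], a[2]), 2 * max(a[3:6]))
})

test_that("drag follows the lift/drag-ratio rule and stays nonnegative", {
  expect_equal(drag_from_lift(0.1, 2), 0.05)
  expect_equal(drag_from_lift(0), 0)
  expect_equal(drag_from_lift(c(-0.2, 0.4), 2), c(0.1, 0.2))
  expect_error(drag_from_lift(1, 0), "positive")
  expect_error(drag_from_lift(1, -2), "positive")
  # symmetric up/down |L| makes drag even-harmonic dominated
  tau <- (0:127) / 128
  D <- drag_from_lift(0.1 * sin(2 * pi * tau), 2)
  a <- harmonic_amplitudes(D, 4)
  expect_gt(a[2], 10 * a[1])
  expect_gt(a[2], 10 * a[3])
})

test_that("assembled force vectors follow the lift/drag geometry", {
  # pure horizontal stroke, lift positive in downstroke, negative in upstroke
  spec <- flapping_spec(5e-3, 0.058, freq = 44.2, stroke_amplitude = 2)
  for (side in c("left", "right")) {
    traj <- source_trajectory(spec, side = side, samples_per_period = 256)
    tau <- traj$phase
    lift <- 0.02 * sin(2 * pi * tau)       # flips sign at stroke reversal
    drag <- drag_from_lift(lift, 2)
    fw <- assemble_force_vector(traj, lift, drag)
    interior <- abs(lift) > 0.2 * max(abs(lift))
    # vertical force positive through both half strokes on both wings
    expect_true(all(fw$force[interior, 3] > 0))
    # wingbeat-mean horizontal drag force cancels for symmetric strokes
    drag_force <- -drag * flaphum:::.safe_unit_rows(traj$velocity)
    expect_lt(abs(mean(drag_force[, 1])), 1e-12 * max(abs(drag_force)))
  }
  # zero inputs give zero force
  traj <- source_trajectory(spec, samples_per_period = 256)
  fw0 <- assemble_force_vector(traj, rep(0, 256), rep(0, 256))
  expect_true(all(fw0$force == 0))
  expect_error(assemble_force_vector(traj, rep(NA_real_, 256), rep(0, 256)),
               "finite")
  expect_error(assemble_force_vector(traj, rep(0, 100), rep(0, 100)), "grid")
})

test_that("left and right lateral forces cancel for symmetric inputs", {
  mod <- hb_model()
  lat <- mod$forces$left$force[, 2] + mod$forces$right$force[, 2]
  expect_lt(max(abs(lat)), 1e-14)
})

test_that("every paradigm preset supports the body weight to 1e-10 relative", {
  for (g in paradigm_groups()) {
    mod <- preset_model(g, samples_per_period = 256)
    mg <- mod$spec$mass * mod$med$gravity
    vert <- mean(mod$forces$left$force[, 3] + mod$forces$right$force[, 3])
    expect_lt(abs(vert - mg) / mg, 1e-10)
  }
})

test_that("force assembly and net-force decomposition are mutually inverse", {
  spec <- hb_spec()
  traj <- source_trajectory(spec, side = "left", samples_per_period = 256)
  tau <- traj$phase
  lift <- 0.02 * sin(2 * pi * tau) + 0.005 * sin(4 * pi * tau)
  drag <- drag_from_lift(lift, 2.5)
  fw <- assemble_force_vector(traj, lift, drag)
  rec <- decompose_net_force(2 * fw$force, traj)
  vmag <- sqrt(rowSums(traj$velocity^2))
  away <- vmag > 0.05 * max(vmag)          # reversal direction is carried over
  expect_lt(max(abs(rec$lift[away] - lift[away])) / max(abs(lift)), 1e-9)
  expect_lt(max(abs(rec$drag[away] - drag[away])) / max(abs(lift)), 1e-9)
  # constant vertical net force with a purely horizontal stroke -> no drag,
  # lift sign flips with the stroke direction
  flat <- flapping_spec(5e-3, 0.058, freq = 44.2, stroke_amplitude = 2)
  ftraj <- source_trajectory(flat, side = "left", samples_per_period = 256)
  fvmag <- sqrt(rowSums(ftraj$velocity^2))
  faway <- fvmag > 0.05 * max(fvmag)
  net <- cbind(0, 0, rep(0.0981, 256))
  dec <- decompose_net_force(net, ftraj)
  expect_lt(max(abs(dec$drag[faway])), 1e-12)
  expect_equal(abs(dec$lift[faway]), rep(0.0981 / 2, sum(faway)),
               tolerance = 1e-9)
  expect_true(all(decompose_net_force(matrix(0, 256, 3), traj)$lift == 0))
  expect_error(decompose_net_force(matrix(0, 100, 3), traj), "grid")
})

test_that("frequency mixing stage (i): first-harmonic lift yields second-harmonic vertical force", {
  spec <- hb_spec()
  mod <- hum_model(spec, lift = function(tau) 0.02 * sin(2 * pi * tau),
                   lift_drag_ratio = 1e9,      # isolate the lift pathway
                   samples_per_period = 256)
  a <- harmonic_amplitudes(mod$forces$left$force[, 3], 4)
  expect_gt(a[2], 0.05 * a[1] + 1e-9)
})

test_that("zero-phase Butterworth filtering matches its analytic response", {
  fs <- 4096
  t <- (0:(fs - 1)) / fs
  # constant passes bit-exactly
  expect_identical(lowpass_forces(rep(1.23, 512), 8, 180, fs), rep(1.23, 512))
  # 44.2 Hz tone through a 180 Hz cutoff: amplitude preserved within 1%
  x <- sin(2 * pi * 44.2 * t)
  y <- lowpass_forces(x, 8, 180, fs)
  mid <- 1025:3072
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
  # 400 Hz tone: attenuated by more than 20 dB
  x <- sin(2 * pi * 400 * t)
  y <- lowpass_forces(x, 8, 180, fs)
  expect_lt(20 * log10(max(abs(y[mid]))), -20)
  expect_error(lowpass_forces(x, 8, 3000, fs), "Nyquist")
})
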