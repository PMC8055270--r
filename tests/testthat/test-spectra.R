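test_that("SPL definition, Parseval and dB round trips are exact", {
  sr <- 4096
  x <- make_test_signal("sine", sr, 1, freq = 64, amplitude = 0.02 * sqrt(2))
  sp <- spl_spectrum(x)
  expect_equal(max(sp$spl), 60, tolerance = 1e-6)   # rms 0.02 Pa = 60 dB
  expect_equal(sp$frequency[which.max(sp$spl)], 64)
  # Parseval with the rectangular window
  expect_lt(abs(sum(sp$mean_square) - mean(x^2)) / mean(x^2), 1e-8)
  # dB <-> Pa^2 round trip
  ms <- c(1e-10, 3.7e-4, 2)
  expect_equal(spl_to_ms(ms_to_spl(ms)), ms, tolerance = 1e-12)
})

test_that("two-tone bin powers match the analytic split", {
  sr <- 4096
  x <- make_test_signal("two_tone", sr, 1, freq = c(100, 250),
                        amplitude = c(1, 0.5))
  sp <- spl_spectrum(x)
  expect_equal(sp$mean_square[sp$frequency == 100], 1^2 / 2, tolerance = 1e-6)
  expect_equal(sp$mean_square[sp$frequency == 250], 0.5^2 / 2, tolerance = 1e-6)
  other <- !(sp$frequency %in% c(100, 250))
  expect_lt(sum(sp$mean_square[other]), 1e-20)
})

test_that("a zero trace is flagged non-physical", {
  x <- rep(0, 1024)
  attr(x, "sample_rate") <- 1024
  sp <- spl_spectrum(x)
  expect_true(attr(sp, "all_zero"))
  expect_true(all(sp$spl < -300))
})

test_that("harmonic bands collect tone power and respect subset bounds", {
  sr <- 44.2 * 256
  x <- make_test_signal("sine", sr, 256 / sr * 18, freq = 44.2)
  attr(x, "freq") <- 44.2
  ht <- harmonic_bands(spl_spectrum(x), freq = 44.2)
  expect_equal(ht$band_ms[1], 0.5, tolerance = 1e-9)
  expect_lt(max(ht$band_ms[2:10]), 1e-18)
  expect_lte(sum(ht$band_ms), attr(ht, "total_ms") * (1 + 1e-12))
  expect_equal(power_concentration(ht, 1), 1, tolerance = 1e-9)
  # monotone in k
  expect_gte(power_concentration(ht, 10), power_concentration(ht, 4))
  expect_error(harmonic_bands(spl_spectrum(x), freq = 4), "overlap")
})

test_that("power concentration rejects zero power", {
  x <- rep(0, 2048)
  attr(x, "sample_rate") <- 2048
  ht <- harmonic_bands(spl_spectrum(x), freq = 50)
  expect_error(power_concentration(ht, 2), "total")
})

test_that("summed-array spectra behave coherently", {
  mod <- hb_model()
  tr <- pressure_eq1(mod, c(0, 0, 1), n_periods = 18)
  sp1 <- spl_spectrum(tr)
  sps <- summed_array_spectrum(list(tr))
  expect_equal(sps$mean_square, sp1$mean_square, tolerance = 1e-12)
  # two identical traces: +6.02 dB everywhere meaningful
  sp2 <- summed_array_spectrum(list(tr, tr))
  sel <- sp1$mean_square > 1e-30
  expect_equal(sp2$spl[sel] - sp1$spl[sel],
               rep(20 * log10(2), sum(sel)), tolerance = 1e-9)
  # antiphase pair cancels to the floor
  tr_neg <- tr
  tr_neg$p <- -tr$p
  sp0 <- summed_array_spectrum(list(tr, tr_neg))
  expect_lt(sum(sp0$mean_square), 1e-25)
  # grid mismatch is an error
  tr_bad <- pressure_eq1(mod, c(0, 0, 1), n_periods = 2)
  expect_error(summed_array_spectrum(list(tr, tr_bad)), "mismatch")
})

test_that("harmonic band SPLs are resolution-invariant", {
  obs <- c(0.4, 0.3, 0.9)
  h1 <- harmonic_bands(spl_spectrum(pressure_eq1(hb_model(256), obs, 18)))
  h2 <- harmonic_bands(spl_spectrum(pressure_eq1(hb_model(512), obs, 18)))
  expect_lt(max(abs(h1$band_spl[1:6] - h2$band_spl[1:6])), 0.05)
})

test_that("test signals are deterministic with documented statistics", {
  x <- make_test_signal("sine", 1024, 1, freq = 100, amplitude = 1)
  expect_equal(rms(x), 1 / sqrt(2), tolerance = 1e-6)
  n1 <- make_test_signal("bandlimited_noise", 1024, 1, cutoff = 200, seed = 7)
  n2 <- make_test_signal("bandlimited_noise", 1024, 1, cutoff = 200, seed = 7)
  expect_identical(n1, n2)
  sp <- spl_spectrum(n1)
  expect_lt(sum(sp$mean_square[sp$frequency > 210]), 1e-20)
  expect_error(make_test_signal("chirp"), "arg")
})

test_that("WAV export writes a valid float32 mono file", {
  x <- sin(2 * pi * 40 * (0:999) / 1000)
  path <- tempfile(fileext = ".wav")
  write_wav(x, path, sample_rate = 1000)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, 4))
  expect_identical(readChar(con, 8), "WAVEfmt ")
  invisible(readBin(con, integer(), 1, 4))
  expect_identical(readBin(con, integer(), 1, 2), 3L)  # IEEE float
  expect_identical(readBin(con, integer(), 1, 2), 1L)  # mono
  expect_identical(readBin(con, integer(), 1, 4), 1000L)
  invisible(readBin(con, integer(), 2, 2))
  invisible(readBin(con, integer(), 1, 4))
  expect_identical(readChar(con, 4), "data")
  nb <- readBin(con, integer(), 1, 4)
  expect_identical(nb, 4000L)
  y <- readBin(con, numeric(), 1000, size = 4)
  expect_equal(y, x, tolerance = 1e-6)
})
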