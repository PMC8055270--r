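test_that("the scaling-law prefactor and pigeon example match direct arithmetic", {
  pref <- scaling_prefactor()
  expect_equal(signif(pref, 2), 2.5e-6)
  expect_equal(as.numeric(power_law(0.4, 1, 7)), pref * (0.4 * 7)^2)
  expect_equal(signif(as.numeric(power_law(0.4, 1, 7)), 3), 1.94e-5,
               tolerance = 0.02)
  # doubling mass or frequency quadruples the law
  expect_equal(as.numeric(power_law(0.8, 1, 7) / power_law(0.4, 1, 7)), 4)
  expect_equal(as.numeric(power_law(0.4, 1, 14) / power_law(0.4, 1, 7)), 4)
  # strict monotonicity in each argument
  expect_gt(power_law(0.5, 1, 7), power_law(0.4, 1, 7))
  expect_gt(power_law(0.4, 1.2, 7), power_law(0.4, 1, 7))
  expect_error(power_law(-1, 1, 7), "positive")
})

test_that("species sweep is consistent with the standalone power pipeline", {
  grid <- synthetic_species_grid(n = 2, mass_range = c(4e-3, 8e-3))
  res <- species_sweep(grid, n_nodes = 32, samples_per_period = 128)
  rec <- grid[1, ]
  preset <- make_preset(rec$group, mass = rec$mass_kg,
                        wing_length = rec$wing_length_m,
                        freq = rec$flap_freq_hz,
                        stroke_amplitude = rec$stroke_amp_rad)
  mod <- hum_model(preset$spec, weight_support = preset$profile,
                   samples_per_period = 128)
  P <- radiated_power(mod, 2 * 343 / rec$flap_freq_hz, n_nodes = 32)
  expect_identical(res$p_sim[1], P)
  # simulated power within order of magnitude of the scaling law
  expect_lt(abs(log10(res$p_sim[1] / res$p_law[1])), log10(3.5))
})

test_that("an isometric grid recovers slope 1 against the predictor and 4/3 against mass", {
  grid <- synthetic_species_grid(n = 6, mass_range = c(2e-3, 6e-2))
  res <- species_sweep(grid, n_nodes = 64, samples_per_period = 128)
  fit_x <- fit_allometry(res, "predictor")
  expect_equal(fit_x$slope[fit_x$group == "all"], 1, tolerance = 0.05)
  fit_m <- fit_allometry(res, "mass")
  expect_equal(fit_m$slope[fit_m$group == "all"], 4 / 3, tolerance = 0.05)
})

test_that("log-log fitting is exact on collinear data", {
  fake <- structure(data.frame(name = letters[1:4], group = "hummingbird",
                               mass_kg = c(1, 2, 4, 8) * 1e-3,
                               wing_length_m = 0.05, flap_freq_hz = 40,
                               stroke_amp_rad = 2,
                               p_sim = 3e-8 * c(1, 2, 4, 8)^1.5,
                               p_law = 1, predictor = c(1, 2, 4, 8)),
                    class = c("scaling_result", "data.frame"))
  fit <- fit_allometry(fake, "predictor")
  expect_equal(fit$slope[1], 1.5, tolerance = 1e-10)
  fake$p_sim[1] <- -1
  expect_error(fit_allometry(fake), "positive")
})

test_that("fly-type profiles radiate more than bird-type at equal morphology", {
  base <- list(mass_kg = 5e-3, wing_length_m = 0.058, flap_freq_hz = 44.2,
               stroke_amp_rad = 2)
  two <- data.frame(name = c("as_fly", "as_bird"),
                    group = c("elongated_fly", "generalist_bird"),
                    base, stringsAsFactors = FALSE)
  res <- species_sweep(two, n_nodes = 48, samples_per_period = 128)
  expect_gt(res$p_sim[res$name == "as_fly"], res$p_sim[res$name == "as_bird"])
})

test_that("sweep input validation catches schema and group errors", {
  empty <- synthetic_species_grid(n = 2)[0, ]
  expect_equal(nrow(species_sweep(empty)), 0)
  bad <- synthetic_species_grid(n = 2)
  bad$group <- "pterosaur"
  expect_error(species_sweep(bad), "unmapped")
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(name = "x", mass_kg = 1), f, row.names = FALSE)
  expect_error(read_species_table(f), "missing column")
  file.remove(f)
})
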