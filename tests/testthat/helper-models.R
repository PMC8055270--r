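# Shared small fixtures. Moderate resolutions keep the default run fast
# while staying well above the solver's 64 samples/period floor.

hb_spec <- function(...) make_preset("hummingbird", ...)$spec

hb_model <- function(samples_per_period = 256, ...) {
  preset_model("hummingbird", samples_per_period = samples_per_period, ...)
}

# Stationary vertical dipole F(t) = F0 sin(2 pi f t) z-hat: the classical
# closed-form reference case.
static_dipole <- function(F0 = 1, f = 44.2, samples_per_period = 256) {
  static_point_force(function(t) cbind(0, 0, F0 * sin(2 * pi * f * t)),
                     freq = f, samples_per_period = samples_per_period)
}

# rms of a numeric vector
rms <- function(x) sqrt(mean(x^2))
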