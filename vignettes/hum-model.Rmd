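---
title: "Modelling flapping-wing hum as a moving point force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flapping-wing hum as a moving point force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flaphum)
```

## The model

A hovering animal supports its weight with oscillating aerodynamic forces
on its flapping wings. Those force fluctuations are also an acoustic
source: each wing radiates like a point force located at the spanwise
third-moment radius R₃ (≈ 55 % of wing length for hummingbirds, 58 % for
parrotlets), the station at which the distributed load exerts the same net
torque about the shoulder. The key scale separation is acoustic
compactness: at a hummingbird's wingbeat frequency (44.2 Hz) the wavelength
is λ₁ = a₀/f_w ≈ 7.8 m, over a hundred wing lengths, and even the tenth
harmonic has λ₁₀ ≈ 0.78 m. The wing is therefore acoustically transparent
and its whole loading collapses onto one moving point per wing.

`pressure_eq1()` evaluates the full moving point-force (loading-noise)
equation at retarded time: a nearfield term proportional to the force
itself, decaying as 1/r², and a farfield term proportional to the force
rate of change (plus the radial source acceleration), decaying as 1/r. The
crossover sits at roughly one wavelength. `pressure_eq3()` is the compact
simplification — geometry frozen at the shoulder pivot, Doppler factors
dropped, the source-acceleration effect reduced to its magnitude scale
4Φ₀Rf_w²/a₀ — and `power_law()` is the corresponding order-of-magnitude
radiated power P₀ = 4(mg)²Φ₀²f_w²/(πρ₀a₀³), whose prefactor with standard
air constants is:

```{r}
scaling_prefactor()
```

## Conventions

The frame is right-handed and earth-fixed: x anterior, y toward the
animal's left, z up, shoulder pivot at the origin (wing radius is measured
from the body centre, so no shoulder offset is modelled). The stroke angle
φ is measured in a horizontal stroke plane from the y axis, positive
sweeping forward; deviation θ is the elevation out of that plane; τ = 0 is
the start of downstroke and the downstroke sweeps forward. These choices
are conventions, not measurements: the quantities the package reports
(band levels, axis angles, powers) are invariant to them except for the
sagittal fore/aft sense, which follows "angles > 90° tilt aft".

The drag vector opposes the source velocity; the lift vector is
perpendicular to it, constructed from the cross product of the velocity
direction with the spanwise direction, with the sign fixed per wing side so
that positive lift during downstroke points up on both wings. Lift
therefore flips sign with stroke direction (negative during upstroke), and
a purely first-harmonic lift already produces second-harmonic vertical
force — the first of two frequency-mixing stages (the second is the
pressure equation itself, whose moving geometry mixes force harmonics with
kinematic harmonics). With forces bandlimited at harmonic 4 the radiated
spectrum still contains energy above harmonic 4 for exactly this reason.

## Driving the model

Forces can be supplied as explicit per-wing lift/drag series, or derived
from an aerodynamic *weight-support profile*: the normalised vertical force
(mean exactly one bodyweight) over the wingbeat. Five paradigm presets
parameterise the groups of flapping fliers by one raised-cosine force pulse
per half stroke:

| group | upstroke/downstroke | pulse width (half strokes) | signature |
|---|---|---|---|
| `generalist_bird` | 0 | 1.25 | dominant harmonic 1 |
| `hummingbird` | 0.45 | 1 | harmonics 1 and 2 paired |
| `lepidoptera` | 0.55 | 1 | harmonics 1 and 2 high |
| `compact_fly` | 0.85 | 0.65 | dominant harmonic 2, content to 6 |
| `elongated_fly` | 0.90 | 0.55 | dominant harmonic 2, strong 3–6 |

These shapes are synthetic stand-ins chosen to reproduce each group's
described harmonic signature; digitised measured profiles can be supplied
through the same table interface (`read_in_vivo_tables()`,
`weight_support_profile()`). Three shape decisions matter numerically and
were made on physical grounds:

* **Pulses are C¹ (raised cosine) and vanish at stroke reversal**, as
  measured weight-support traces do. Because the lift/drag *direction*
  flips by 180° at reversal, any residual force magnitude there becomes a
  jump in the force vector, and the farfield pressure (∝ ∂F/∂t) turns a
  jump into a flat spectral plateau across all harmonics.
* **The default deviation kinematics are a figure-of-eight whose second
  harmonic is sine-phased**, crossing zero at the reversals, so the source
  velocity direction rotates smoothly through both reversals instead of
  flipping discontinuously.
* **Input bandlimiting (`harmonic_cutoff`) is a zero-phase periodic
  Butterworth response (order 8, half-power at 1.02× the cutoff
  harmonic)**, the periodic analogue of the zero-phase 8th-order 180 Hz
  filtering applied to measured forces. A sharp Fourier truncation would
  ring (Gibbs) and reintroduce the reversal jumps it is meant to remove.

After assembly the forces are rescaled by a single global factor so that
the wingbeat-mean total vertical force equals m·g exactly (drag and
deviation contributions would otherwise offset it by a fraction of a
percent); the profile shape is preserved.

```{r}
mod <- preset_model("hummingbird", samples_per_period = 256)
mod
```

## Numerical choices

**Exact periodicity everywhere.** All signals are truncated Fourier series,
so time derivatives (source velocity, ∂F/∂t, ∂Mr/∂t) use spectral
differentiation — machine-precision for bandlimited series, no stencil or
endpoint error. The propagation solver computes one emission period,
applies the forward retarded-time map t → t + |r|/a₀ (strictly monotone for
subsonic sources; violation raises an error), cubic-resamples one observer
period on a uniform grid, and tiles it: the steady state is exact and no
startup transient exists. Traces default to 18 wingbeats so the FFT
resolution f_w/18 ≈ 2.46 Hz resolves the ±2.5 Hz harmonic bands.

**Sampling.** 1024 samples per period by default (oversampling harmonic 10
by two orders of magnitude); field maps and sweeps use 256–512 for speed,
and harmonic band levels are stable to < 0.05 dB under resolution doubling.

**Spectra.** The default window is rectangular over an exact integer
number of wingbeats — leakage-free for periodic signals, with Parseval
holding exactly; Hann is available for measured records. SPL is referenced
to 20 µPa (configurable — the reference of externally reported absolute
levels is not always stated, so relative, inter-harmonic levels are the
robust comparison). `power_concentration()` uses total *acoustic* power as
its denominator: the DC bin, a static nearfield offset, is not radiated
sound and is excluded.

**Spherical integration.** Radiated power integrates p²rms/(ρ₀a₀) over a
Fibonacci (equal-area) lattice, so the quadrature is an unweighted mean;
512 nodes hold dipole-type integrands to ≈0.1 %. In the nearfield the
surface integral is not radius-invariant (the 1/r² term contributes
(λ/2πr)² relatively — 1.5 % at 10 m for 44.2 Hz), so `radiated_power()`
warns inside one wavelength; farfield invariance is within 2 % on a
10–30 m ladder.

**Principal directivity axes.** Sections are sampled on rings in the
sagittal or coronal plane; the two angular minima of the 3-point smoothed
polar curve define the waistline, whose axial mean (doubling angles) gives
the waist orientation; the reported axis is its perpendicular, folded into
[0°, 180°), ties broken toward the smaller angle. For bilaterally
symmetric hover the coronal axis is pinned to 90° at every harmonic.

**Distributed sources.** `pressure_distributed()` places n stations at the
centres of equal-width strips of a uniform-chord wing, with
linear-in-radius force shares conserving both total force and total torque
(hence n = 1 reduces to the single point at R₃). At hummingbird scale the
1-source and 10-source spectra differ by well under 0.5 dB per band —
the compactness property in action.

**Reversal singularities.** Where |v| < 10⁻⁶ of its peak the lift/drag
directions are undefined and are carried over from the nearest valid
sample.

## Accuracy against closed forms

The solver is validated against the stationary oscillating point force
(dipole): farfield amplitude 2πfF₀cosθ/(4πa₀r) and radiated power
(2πf)²F₀²/(24πρ₀a₀³) to within 1 %, near/far decay exponents −2/−1 to
±0.02, and a rotated dipole's principal axis to ±0.5°:

```{r}
dip <- static_point_force(function(t) cbind(0, 0, sin(2 * pi * 44.2 * t)),
                          freq = 44.2, samples_per_period = 256)
c(simulated = radiated_power(dip, 30, n_nodes = 256),
  closed_form = (2 * pi * 44.2)^2 / (24 * pi * 1.23 * 343^3))
```

The simplified equation tracks the full one closely where the hum's power
lives: dominant bands to < 0.25 dB and broadband rms to ~1 % at hummingbird
scale. Individual weak bands (those sitting near a directivity waist,
carrying ~1 % of the power) can deviate by up to ~2 dB, because the
simplification drops source-motion (Doppler) mixing; comparisons of the
two forms should therefore be read per dominant band or in integrated
power, not on near-null bands.

## Allometric sweeps

`species_sweep()` rebuilds the full pipeline per species — group profile
normalised to the species' weight, kinematics at its Φ₀ and f_w, power
integrated at a radius of 2λ₁ so the geometry stays acoustically similar —
and `fit_allometry()` fits log–log slopes against mass or the scaling-law
predictor. On a synthetic isometric grid (R ∝ m^{1/3}, f_w ∝ m^{−1/3},
fixed profile and Φ₀) every dimensionless group of the model is constant,
so simulated power is exactly proportional to the predictor; the fitted
slope of 1 validates the machinery rather than any biological claim:

```{r}
res <- species_sweep(synthetic_species_grid(n = 5), n_nodes = 48,
                     samples_per_period = 128)
fit_allometry(res, "predictor")[1, c("group", "slope", "n")]
```

Default stroke amplitudes are order-one radians (2 rad), with the
documented shallow-stroke override (0.7 rad) for elongated flies; records
may override per species. The literature compilations of species
morphology are deliberately not bundled — the CSV schema
(`name, group, mass_kg, wing_length_m, flap_freq_hz[, stroke_amp_rad]`)
accepts them, and `synthetic_species_grid()` generates test ladders.

## What the synthetic fixtures do and do not show

The generator reproduces the *structure* of the in vivo study inputs:
periodic stroke/deviation series with the described harmonic ranking,
weight-support profiles with each group's harmonic signature, normalisation
of mean vertical force to bodyweight, and forces bandlimited beyond the
fourth harmonic. It does not reproduce the measured curves themselves, so
tests passing on fixtures validate the physics and the pipeline — decay
laws, symmetry-forced axes, compactness, power concentration, scaling
collapse — but not the per-harmonic absolute SPLs of a particular bird,
which require ingesting the deposited recordings via
`read_in_vivo_tables()` (filter settings: forces 8th order at 180 Hz,
kinematics 4th order at 400 Hz, both zero-phase on tiled periodic records).

## Known limitations

* No scattering by body or wings (justified by compactness), no
  atmospheric absorption, no room reflections, no quadrupole turbulence
  noise, no feather sonation or flutter: the model covers the
  loading-noise hum only.
* Rigid-airfoil idealisation: wing twist, deformation and pitch dynamics
  enter only through whatever lift/drag series the user supplies.
* The bilateral half-split of net measured force assumes symmetric hover.
* The quasi-steady lift/drag ratio defaults to a constant 2.0 standing in
  for measured hummingbird polars; supply a tabulated ratio where it
  matters.
* Absolute SPLs depend on the chosen reference pressure; inter-harmonic
  (relative) levels are the reference-free quantity.
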