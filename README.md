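# flaphum — aeroacoustics of flapping-wing hum

Hovering hummingbirds, flies, moths and small birds radiate a characteristic
hum: the air-pressure signature of the oscillating lift and drag forces that
their flapping wings generate to support their body weight. Because a
flapping wing is tiny compared with the wavelength at the wingbeat frequency
(R/λ₁ ≈ 0.007 for a hummingbird), each wing can be collapsed to a single
equivalent point force at the spanwise third-moment radius R₃ ≈ 0.55 R.
`flaphum` implements that model end to end for bioacousticians and
biomechanists: it synthesises the acoustic near- and farfield of a flapping
animal from its wingbeat kinematics and per-wing forces, and analyses the
result the way microphone-array studies do.

The core is the moving point-force (loading-noise) equation. With r the
vector from the source point to the observer, M = v_R3/a₀ the source Mach
vector, and Mr its line-of-sight component, the pressure evaluated at
retarded time is

```
p = [ 1/(4π|r|²(1−Mr)²) ( (1−M²)/((1−Mr)|r|) (r·F) − F·M ) ]   (nearfield, ∝ 1/r²)
  + [ 1/(4πa₀|r|²(1−Mr)²) ( r·∂F/∂t + (∂Mr/∂t)/(1−Mr) (r·F) ) ] (farfield, ∝ 1/r)
```

per wing, summed over wings (and optionally over spanwise stations). A
compact simplified form (pivot-referenced, Doppler-free, with the source
acceleration scale 4Φ₀R f_w²/a₀) and the radiated-power scaling law

```
P₀ = 4 F₀² Φ₀² f_w² / (π ρ₀ a₀³),   F₀ = m g   (prefactor ≈ 2.5×10⁻⁶ kg⁻¹ s⁻¹)
```

are provided for cross-species work. Synthetic paradigm presets (elongated
flies, compact flies, moths/butterflies, hummingbirds, generalist birds)
encode the distinct harmonic signatures of each group's aerodynamic
weight-support profile; measured kinematics/force tables can be ingested
from delimited text instead.

## Worked example

```r
library(flaphum)

mod <- preset_model("hummingbird")        # 5 g, R = 0.058 m, fw = 44.2 Hz
tr  <- pressure_eq1(mod, observer(c(0, 0, 1), "overhead"))
ht  <- harmonic_bands(spl_spectrum(tr))
head(as.data.frame(ht), 4)
#>   harmonic frequency      band_ms band_spl
#> 1        1      44.2 5.56e-06      41.4
#> 2        2      88.4 3.13e-05      48.9
#> 3        3     132.6 1.02e-06      34.1
#> 4        4     176.8 7.01e-08      22.4

principal_axis(directivity_section(mod, "coronal", 10, band = 2))
#> [1] 90
radiated_power(mod, 10, n_nodes = 256)
#> [1] 2.85e-07
power_law(5e-3, 2, 44.2)
#> [1] 4.82e-07
```

Reading the output: one metre above the bird the hum carries most of its
energy in the first two wingbeat harmonics (41.4 and 48.9 dB re 20 µPa —
"paired" levels are what make the hummingbird hum rather than whoosh), with
band levels falling steeply beyond the fourth harmonic. The second-harmonic
dipole points straight up (principal axis 90°: vertical weight support,
bilaterally symmetric hover). The integrated radiated power (0.29 µW) sits
within a factor of two of the scaling-law estimate (0.48 µW), which is the
law's intended order-of-magnitude accuracy.

A thin CLI wraps the same functions:

```sh
exec/flaphum simulate   --config run.yaml     # traces, spectra, harmonic tables, WAV
exec/flaphum directivity --config run.yaml    # sections + principal-axis report
exec/flaphum sweep --species species.csv      # scaling sweep + allometric fits
```

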