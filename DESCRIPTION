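Package: flaphum
Title: Aeroacoustics of Flapping-Wing Hum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the acoustic pressure field radiated by the oscillating
    lift and drag forces of flapping animal wings, modelled as moving point
    forces evaluated at retarded time. Provides periodic wingbeat kinematics,
    per-wing force assembly from weight-support profiles, near/farfield
    pressure synthesis at arbitrary observers, harmonic sound-pressure-level
    spectra, dipole directivity sections with waistline principal axes,
    spherically integrated radiated acoustic power, and allometric
    scaling-law sweeps across species. Includes synthetic paradigm presets
    for elongated flies, compact flies, moths, hummingbirds and generalist
    birds, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
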