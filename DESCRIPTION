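Package: sipmsim
Title: Silicon Photomultiplier Simulation and Photon-Transfer Analysis for
    High-Speed Laser Scanning Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven Monte Carlo simulation of silicon photomultiplier
    (SiPM) microcell arrays under Poisson illumination, photon-transfer-curve
    (PTC) estimation of absolute photon flux and detector gain with
    equivalent-bandwidth correction, a signal-chain model (two-exponential
    single-photon response, pole-zero cancellation, lowpass filtering,
    amplifier clipping, bias-supply droop), fluorophore excitation kinetics
    under pulsed two-photon excitation versus laser repetition rate, and
    shot-noise signal-to-noise accounting for resonant-scanned imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
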