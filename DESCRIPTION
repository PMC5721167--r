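Package: pulsead
Title: Reduced-Order Compliant Haemodynamics of Aortic Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter (0D) and quasi-one-dimensional pulse-wave
    modelling of the dissected aorta. Provides three-element Windkessel
    (RCR) outlet models with backward-Euler coupling, a patient-specific
    four-step Windkessel tuning procedure driven by brachial pressures and
    branch mean flows, a compliant-vessel pulse-wave solver with a linear
    moving-boundary wall law derived from area compliance, a true/false
    lumen dissection model with a single entry tear, Carreau-Yasuda blood
    rheology, and clinical post-processing indices (foot-to-foot pulse-wave
    velocity, normalized area variation, TAWSS, OSI, transmural pressure,
    systolic stored volume). Synthetic waveform and geometry generators
    stand in for patient imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
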