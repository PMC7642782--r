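Package: sfxsad
Title: Still-Diffraction Simulation, Monte Carlo Merging and Anomalous
    Signal Metrics for Serial Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis machinery for native-SAD phasing studies in
    serial femtosecond crystallography (SFX). Simulates still-diffraction
    datasets from randomly oriented microcrystals with partial Bragg
    intensities, per-crystal scales and sulfur anomalous scattering; merges
    partial intensities in a Monte Carlo manner with per-crystal scaling,
    spherical-cap partiality correction and post-refinement; optimizes the
    sample-to-detector distance by minimizing the spread of per-pattern
    unit-cell estimates; and computes the half-dataset and anomalous
    data-quality indicators used to judge phasing feasibility (R_split,
    CC_1/2, CC*, CC_ano, S_ano from phased anomalous difference Fourier
    maps, and model-versus-data anomalous correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
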