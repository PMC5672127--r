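Package: qamskit
Title: Single-Marker Multi-Component Quantitation for HPLC-DAD Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements quantitative analysis of multicomponents by single
    marker (QAMS) for HPLC-DAD data: relative correction factors from linear
    calibration slopes, relative-retention-time peak location, external-standard
    comparison, and the standard analytical method-validation statistics
    (linearity, LOD and LOQ, RSD-based precision, recovery, durability).
    Includes chromatogram readers and writers, baseline estimation, peak
    detection and integration, system-suitability metrics (theoretical plates,
    resolution), and a seeded synthetic chromatogram generator for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
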