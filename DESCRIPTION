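Package: NOxMonitor
Title: Optical Nitrification Monitoring from UV-Vis Absorbance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to monitor nitrification in chloraminated drinking water from
    time-stamped UV-Vis absorbance spectra. Compensates for monochloramine decay
    with per-wavelength linear models anchored at the 245 nm absorbance offset,
    isolates the combined nitrate + nitrite (NOx-) difference spectrum relative
    to a baseline, and quantifies relative NOx-N concentration with a
    support-vector regression calibrated on standards, raising alerts when the
    change exceeds a nitrification threshold. Includes a Beer-Lambert synthetic
    spectra generator (component bands, mixtures, and chloramine-decay /
    nitrification time courses with known ground truth) so the full pipeline is
    testable without instrument data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'spectra-io.R'
    'spectra-ops.R'
    'synthetic.R'
    'compensation.R'
    'regression.R'
    'monitor.R'
    'cli.R'
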