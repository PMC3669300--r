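Package: caspikes
Title: Model-Based Analysis of Calcium Spikes in Confocal Line-Scan Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of calcium spikes recorded by laser-scanning
    confocal microscopy in line-scan (x-t) mode. Provides a phenomenological
    kinetic model of the spike fluorescence time course with numerically derived
    descriptors (amplitude, time to peak, full duration at half-maximum),
    per-pixel acquisition-time correction for unidirectional and bidirectional
    scanning, extraction of background-subtracted dF/F0 traces from x-t images,
    constrained nonlinear least-squares fitting with nested-model F-test
    acceptance, a synthetic-spike simulator for the OG-5N and Fluo-3 indicator
    regimes, and a benchmarking harness for algorithm comparison, timing-error
    and detectability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
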