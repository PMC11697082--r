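Package: hrtoct
Title: Heart-Retina Time from ECG-Coupled Time-Resolved OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrocardiogram-coupled time-resolved
    dynamic optical coherence tomography (OCT). Converts B-scan intensity time
    series into fringe-washout axial blood-flow velocity profiles, detects
    pulse-arrival times at retinal arterioles, detects ECG R-peaks
    (Engelse-Zeelenberg detector), and cross-correlates the two event trains to
    estimate the heart-retina time (HRT). Includes rigid B-scan registration,
    coefficient-of-variation reproducibility reports, and a forward-model
    synthetic-data generator with known ground truth so that every stage is
    testable without acquisition hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
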