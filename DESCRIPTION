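Package: ceusquant
Title: Quantification of Contrast-Enhanced Ultrasound Cine Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Region-of-interest based quantification of bolus-injection
    contrast-enhanced ultrasound (CEUS) recordings. Reads multi-page TIFF
    cine loops, rasterizes circular, rectangular and polygonal regions of
    interest, extracts time-intensity curves and computes per-region
    perfusion metrics (peak enhancement, trapezoidal area under the curve,
    artery-normalized AUC, contrast arrival time, five-phase bolus
    segmentation), flags motion-contaminated clips, aggregates per-patient
    metrics into cohort summary tables with paired t-tests, and ships a
    seeded synthetic speckle cine and cohort generator for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
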