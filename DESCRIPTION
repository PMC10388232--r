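Package: gaitdtw
Title: Gait Improvement Scoring from Force-Plate Recordings by Dynamic Time Warping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying recovery of human gait from vertical
    ground-reaction-force (GRF) recordings, such as before and after total
    knee arthroplasty. Force-plate traces are read from delimited text,
    trimmed, gap-filled and segmented into stance-phase steps; each step is
    amplitude-normalized and compared to a healthy-gait reference with an
    exact dynamic time warping (DTW) distance; per-subject distances are
    normalized to the pre-treatment condition so that an improvement
    percentage can be reported. A seeded synthetic GRF generator produces
    five-phase healthy and phase-attenuated impaired stance curves with
    plate noise, quantization and saturation, so the whole pipeline is
    testable without patient data. Includes cohort demographic summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
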