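Package: rdfwave
Title: Regional Dominant Frequency and Wave Break Rate Analysis of
    Intracardiac Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-processing toolkit for multichannel bipolar intracardiac
    electrograms recorded during atrial fibrillation. Conditions each channel
    into a smooth activation envelope, averages the channels of a mapping
    catheter into one regional signal, smooths it with a two-sided exponential
    FIR kernel, and tracks the instantaneous regional dominant frequency
    (iRDF) with a short-time Fourier transform. From the iRDF series it
    derives the regional dominant frequency (RDF, the upper quartile of iRDF),
    detects wave breaks (transient drops of iRDF below the RDF), and computes
    the wave break rate (WBR). Includes per-patient site classification,
    64-level color maps for electroanatomic geometries, segment-duration
    stability analysis, cohort statistics, and a seeded synthetic electrogram
    simulator with ground-truth activation schedules for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
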