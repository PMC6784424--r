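Package: pbrtqc
Title: Optimization of Moving Average Quality Control Procedures by Bias
    Detection Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for patient-based real-time quality control (PBRTQC) in
    clinical chemistry. Computes truncation-filtered moving averages (simple
    MA and EWMA) over ordered patient-result streams, derives min/max control
    limits from unbiased data, simulates systematic bias injection to measure
    the number of results until detection, and ranks candidate MA procedures
    by their ability to detect a clinically significant bias (the allowable
    total error, TEa) within a laboratory's daily testing volume. Includes a
    seeded generator of LIS-like synthetic result streams so the whole
    pipeline can be exercised without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
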