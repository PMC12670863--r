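Package: cmrqa
Title: Multilevel Reader Comparison and Quality Assurance for Cardiovascular MR Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two readers' contour annotations of cardiovascular
    magnetic resonance (CMR) images on three linked levels: segmentation
    metrics (Dice similarity, Hausdorff distance, per-slice milliliter
    impact), clinical parameters (Simpson slice-summation ventricular
    volumes, ejection fractions, myocardial and scar mass, global T1/T2
    mapping values, area-length atrial volumes), and study statistics
    (bias confidence intervals judged against tolerance ranges derived
    from intrareader variability). Detects per-case outliers, traces
    quantitative parameter differences to their causal slice-level
    contour differences, aggregates segmentation quality by cardiac
    position, and emits comparison reports. A synthetic phantom-cohort
    generator with analytic ground truth makes every pipeline stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    polyclip,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
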