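Package: phenoflag
Title: Context-Aware Consistency Checking for Volunteered Phenological
    Observations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated quality control for volunteered flowering-onset
    records. Each observation is characterised by eleven contextual
    variables (latitude, longitude, elevation and eight climate sums
    accumulated from 1 January to the reported onset day), embedded to two
    dimensions with an exact t-SNE, grouped into contextually homogeneous
    clusters by Gaussian mixtures under ten constrained covariance
    parameterisations selected by BIC, and flagged as inconsistent when
    the onset day of year falls outside the Tukey fences of its cluster.
    Includes tools to quantify how flagged observations bias long-term
    trend estimates, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
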