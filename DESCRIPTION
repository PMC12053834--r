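Package: volcanofit
Title: Automated Construction and Validation of Empirical Volcano Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits continuous piecewise-linear (segmented) models to
    catalyst and enzyme descriptor-activity data by weighted least
    squares with iterative breakpoint refinement, selects the number of
    breakpoints by the Bayesian information criterion, classifies the
    resulting trend (sharp volcano, plateau volcano, monotonic, flat,
    inverted, or statistically invalid), locates the activity peak with
    an uncertainty band, flags outliers by robust covariance, and
    screens operator-augmented descriptor pools for the best volcano
    relationship. Includes a synthetic-data generator with known
    piecewise ground truth and a command-line interface for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    MASS,
    jsonlite
Suggests:
    readxl,
    yaml,
    optparse,
    segmented,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
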