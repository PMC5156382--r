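Package: climwindow
Title: Climate Window Analysis by Exhaustive and Weighted Window Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the time period over which a climate
    variable best explains a biological response. Provides exhaustive
    sliding-window search over all candidate windows with corrected-AIC
    (AICc) model selection, parametric weighted-window analysis using
    Weibull or generalised extreme value weight curves fitted by bounded
    quasi-Newton optimisation, multi-model inference (Akaike weights,
    confidence sets, model averaging, median windows), randomization-based
    error metrics, k-fold cross-validated AICc, and a synthetic-data
    generator for calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
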