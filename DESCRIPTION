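Package: microeda
Title: Microclimate and Electrodermal Activity Analysis for DIY Wearables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking localized environmental conditions
    (microclimate) to sympathetic arousal measured as electrodermal
    activity (EDA) from low-cost wrist-worn sensors. Converts raw
    exosomatic voltage readings to skin conductance, preprocesses the
    signal (anti-aliased resampling, high-order Butterworth filtering in
    second-order sections, normalization, smoothing, z-score outlier
    masking), decomposes conductance into tonic and phasic components by
    sparse convex optimization with a biexponential sudomotor response
    kernel, and derives the standard time- and frequency-domain indices
    (SCL, NSSCR, dphEDA, EDASymp, TVSymp, MTVSymp). Features are
    synchronized with environmental logs, windows are labeled from
    self-reported difficulty and stress, and the association screening
    (Kolmogorov-Smirnov, Fisher's ratio, Spearman) and two-way
    random-forest / support-vector / linear model comparison with
    Shapley-value attribution are provided, together with a synthetic
    session generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    splines,
    quadprog,
    stats,
    utils,
    jsonlite,
    ranger,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
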