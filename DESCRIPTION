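Package: hipperlab
Title: Analysis Pipeline for High-Pressure Gaseous Heart Preservation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing ex-vivo heart preservation
    experiments that use high-pressure gas persufflation followed by
    Langendorff reperfusion assessment. Provides oxygen dosimetry for the
    sealed-chamber gas supply (organ oxygen demand under arrest and
    hypothermia via a Q10 rule, minimum chamber pressure, and pump duty
    cycle), beat detection and hemodynamic summaries from chart-recorder
    pressure and flow traces (heart rate, developed pressure, dP/dt
    extrema, coronary flow, pressure-time integral), infarct planimetry
    from TTC-stained slice images, the associated statistical battery
    (exact Fisher tests, ANOVA, assumption-gated pairwise t-tests with
    Holm correction, Cohen's d, PCA, PerMANOVA, simulation-based power),
    and a seeded synthetic-data generator with ground truth for
    validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    EBImage,
    jsonlite
Suggests: testthat (>= 3.0.0), vegan, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
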