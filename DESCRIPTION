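Package: microstates
Title: EEG Microstate Segmentation, Dynamics, and Condition-Level Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for EEG microstate analysis of multichannel scalp
    recordings: global field power (GFP) computation, extraction of
    topographic maps at GFP peaks, polarity-invariant atomize-and-agglomerate
    hierarchical clustering (AAHC) into microstate template maps, a
    trial / condition / global template hierarchy with optimal label
    alignment, template back-fitting, and extraction of the classical
    microstate dynamics features (duration, occurrence, coverage, and
    transition probabilities). Includes a synthetic-EEG generator with
    planted Markov microstate dynamics for validation, a preprocessing
    layer (zero-phase FIR band filters, epoching, amplitude-based artifact
    rejection, average referencing, baseline removal), repeated-measures
    statistics with the Mauchly / Greenhouse-Geisser / Huynh-Feldt
    sphericity rule, Friedman and Wilcoxon alternatives under normality
    gating, Bonferroni post hocs, and noncentral-distribution power and
    sample-size calculators for paired t-tests and within-subject ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
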