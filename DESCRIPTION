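Package: cupmix
Title: Current-Use Pesticide Mixture Exposure and Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse residue mixtures of current-use pesticides (CUPs) in
    agricultural soil and vegetation sampled along in-field/off-field
    transects over a year. Provides a validated long-format data model with
    explicit left-censoring semantics (LOD/LOQ), a synthetic field-campaign
    generator with known ground truth, mixture summarisation (detection
    frequencies, concentration statistics, mixture-combination enumeration),
    seasonal curve modelling by loess smoothing compared with Kullback-Leibler
    divergence, delta-threshold peak detection on detrended monthly series,
    exponential distance-decay fitting of spray drift with a fixed background
    term, and additive mixture risk and hazard quotients (MRQ for collembola
    and earthworms via NOEC/LC50-derived PNECs, MHQ for a surrogate
    ground-nesting bee via honey-bee contact LD50), with replicate-level
    aggregation and single-compound risk attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
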