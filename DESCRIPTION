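Package: hp13c
Title: Quantification of Hyperpolarised [1-13C]Pyruvate MRI with Linked
    Histology Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification chain for dynamic hyperpolarised
    [1-13C]pyruvate magnetic resonance imaging of prostate cancer: synthetic
    dynamic metabolite image series with known two-site exchange kinetics and
    Rician noise, signal-to-noise ratio mapping with the Rayleigh-corrected
    background estimate, apparent exchange rate constant (kPL) estimation by
    frequency-domain linear least squares with a time-domain oracle, apparent
    diffusion coefficient fitting, compartmentalised digital-pathology
    metabolic metrics (MCT1/MCT4 staining, LDHA/LDHB/PDHA1 transcript counts),
    and tie-aware nonparametric cohort statistics (Spearman correlation
    matrices, exact and tie-corrected Mann-Whitney comparisons, percent
    Gleason pattern 4 grouping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
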