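Package: glycorelax
Title: Time-Domain NMR Relaxometry Analysis of Protein Glycation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying protein glycation from
    benchtop time-domain NMR (TD-NMR) relaxation measurements. Provides
    forward signal models for saturation-recovery, CPMG and IR-CPMG pulse
    sequences, monoexponential T1/T2 fitting, Tikhonov-regularized
    nonnegative 1D and 2D inverse Laplace transforms (relaxation-time
    spectra and T1-T2 correlation maps), proton-pool detection with
    (T2/T1) map-ratio extraction, and a method-agreement layer (min-max
    normalization, MAE, RMSE, correlation p-values, ANOVA with Tukey
    post-test) against a free-amino-group reference assay. A synthetic
    study generator emulates heat-induced glycation of a protein-sugar
    formulation across three temperature arms for validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
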