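Package: seedhtt
Title: Thermal, Hydro and Hydrothermal Time Models for Seed Germination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Population-based threshold models for seed germination
    time courses: thermal time, hydrotime and hydrothermal time models
    fitted by probit regression nested in a grid search over the time
    constants, with base temperature and base water potential estimation.
    Includes a Michel-Kaufmann calibration of PEG-6000 osmotic solutions,
    a synthetic germination-trial generator for parameter-recovery
    validation, percentile (t(g)) extraction from cumulative germination
    curves, and a multivariate stage (PCA with variable contributions and
    cos2, supplementary-variable projection, hierarchical clustering on
    principal components) relating fitted parameters to seed trait
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
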