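Package: amyquant
Title: Quantification of Amyloid PET Imaging with Reference-Region SUVR,
    Partial Volume Correction and Logan Graphical Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Regional quantification of amyloid PET scans: standardized
    uptake values (SUV) and target-to-reference ratios (SUVR) under
    configurable FreeSurfer-based reference-region schemes (cerebellar
    cortex, brainstem, core and total white matter), geometric transfer
    matrix (GTM) / regional spread function (RSF) partial volume
    correction of regional means, Logan graphical analysis for
    distribution volume ratios (DVR, binding potential BP_ND) with a
    reference-tissue input and total volume of distribution (V_T) with an
    arterial plasma input, and a longitudinal statistics layer (change
    metrics, effect sizes, test-retest variability and clinical-trial
    sample-size estimation from rates of amyloid accumulation). Includes
    a synthetic-data module that generates digital label phantoms,
    compartment-model time-activity curves and simulated longitudinal
    cohorts with known ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
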