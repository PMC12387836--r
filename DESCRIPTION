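Package: ppolung
Title: Quantitative CT Lung Volumetrics and Predicted Postoperative Lung Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Hounsfield-unit threshold classification of lung CT volumes into
    well-aerated (functional), emphysematous and non-aerated tissue; per-segment,
    per-lobe and whole-lung volumetrics from a co-registered segment label map;
    simulated anatomical resection with removed/remaining tissue fractions;
    predicted postoperative FEV1 and DLCO under the 5%-per-segment rule, the
    Brunelli regression models and a volumetric model; two-group cohort analysis
    (response split, mean/SD summaries, pooled-variance t-tests, measured versus
    predicted deviations, pre/post best-fit line); and synthetic CT phantoms and
    patient cohorts so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
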