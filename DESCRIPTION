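Package: zosteragrowth
Title: Allometric Estimation of Eelgrass Leaf Growth Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of leaf growth rates in eelgrass (Zostera marina)
    shoot-marking studies: the in situ rate, the leaf-marking rate, the
    allometric projection through the leaf length-to-dry-weight power law,
    and the plastochrone (third-leaf) rate; together with the exact bias
    decomposition that relates them, agreement statistics (RMSE, Lin's
    concordance correlation, regression through the origin), a seeded
    generator of synthetic marking campaigns for validating every identity
    and inequality of the framework, and CSV/YAML input-output for
    campaign-structured leaf records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm
Config/testthat/edition: 3
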