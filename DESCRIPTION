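Package: brass
Title: Bias and Resolvability Attribution Using Split Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis framework for benchmarking single-cell and
    single-transcript measurement methods run in parallel on splits of the
    same culture.  Quantifies resolvability of gene-expression distributions
    across a stimulus series with ROC AUC profiles, parameterizes
    dose-response with weighted Hill fits and normalization to relative
    promoter units, attributes method differences to measurement steps via
    sign and Friedman tests, infers transcriptional burst size and frequency
    from negative-binomial fits to RNA counts, and estimates relative
    hybridization efficiency under a binomial-thinning model.  Includes a
    seeded generator of synthetic split-sample experiments with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    fitdistrplus
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
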