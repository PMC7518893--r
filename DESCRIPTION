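Package: vernadyn
Title: Decomposition and Analysis of FLC Silencing Dynamics in Field
    Vernalization Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the winter-long silencing of the
    Arabidopsis floral repressor FLC in field experiments: qPCR
    reference-gene normalization and quality filtering, detection of the
    VIN3 induction day that separates the two phases of FLC shutdown,
    piecewise estimation of starting levels and phase-specific decline
    rates, comparative statistics (Dunnett many-to-one contrasts,
    REML mixed-model slope contrasts with Satterthwaite tests, an
    asymptotic test for equality of coefficients of variation,
    Benjamini-Hochberg correction), the FLC post-vernalization flowering
    statistic, downstream fitness models, and a synthetic field-experiment
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
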