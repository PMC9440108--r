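Package: paleoseason
Title: Seasonal Temperature Reconstruction and Variance Attribution from
    Mollusk Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A quantitative palaeoecology pipeline from modern
    site-by-taxon assemblage tables to seasonal temperature
    reconstructions and seasonal variance-contribution attribution.
    Provides ordination screening of calibration sets (PCoA, DCA gradient
    length, CCA with variance-inflation filtering, forward selection and
    Monte Carlo permutation tests, NMDS with passive placement of fossil
    samples), transfer-function calibration (weighted averaging, WA-PLS,
    the modern analogue technique, and locally-weighted variants) with
    bootstrap cross-validation and sample-specific errors,
    analogue goodness-of-fit classification, random-reconstruction
    significance testing, sliding-window seasonal variance contributions
    to mean annual temperature, and a synthetic-data generator with
    unimodal species responses for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
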