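Package: manifestFL
Title: Distinctiveness of Multidimensional Instruments via the Manifest Fornell-Larcker Criterion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses discriminant validity (distinctiveness) between the
    dimensions of multidimensional measurement instruments when raw data are
    unavailable, using only Cronbach's alpha, item counts, and the correlation
    matrix between manifest composite scores (the manifest Fornell-Larcker
    criterion, with double and single attenuation correction), alongside the
    original Fornell-Larcker criterion computed from standardized factor
    loadings and latent correlations. Includes a population two-factor model
    toolkit with a maximum-likelihood confirmatory factor analysis fitter, a
    Monte Carlo engine that evaluates all three criteria over a factorial
    design of loading patterns, latent correlations and sample sizes, and
    batch review utilities for published instrument summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
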