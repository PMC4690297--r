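Package: bevnudge
Title: Decision-Analytic Model of Healthy-Beverage Placement in Corner Stores
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decision-analytic simulation of how the placement of healthy
    (non-sugar-sweetened) beverages in corner-store coolers changes the
    probability that an adolescent purchases one. Implements the purchase
    decision tree (preference group, convenience shopper versus browser,
    horizontal cooler and vertical shelf selection shares), exact
    expectation grids relative to the worst placement, a Monte-Carlo
    cohort simulator, a one-way sensitivity-scenario engine with
    mean-preserving spread scaling of the placement effects, and a
    population-level projection of additional healthy-beverage purchases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
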