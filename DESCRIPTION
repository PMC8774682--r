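Package: quenchkin
Title: Enzyme Inhibition Kinetics and Fluorescence-Quenching Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize reversible enzyme inhibitors from
    spectrophotometric and fluorometric titration data: initial rates from
    absorbance progress curves, IC50 estimation by log-logistic regression,
    reversibility diagnostics, Lineweaver-Burk and global Michaelis-Menten
    fits with inhibition-type classification and Ki from the secondary plot,
    first-order inactivation kinetics with transition free-energy changes,
    inner-filter correction, Stern-Volmer and double-logarithmic
    fluorescence-quenching analysis with static/dynamic classification,
    Van't Hoff binding thermodynamics with noncovalent-force typing, and
    synchronous-fluorescence conformation probes (peak shifts and quenching
    ratios for tyrosine and tryptophan channels). A seeded synthetic-data
    generator reproduces the statistical structure of each assay so that
    every fitting routine is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
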