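Package: breathcomplex
Title: Complexity Analysis of Breathing Patterns from Whole-Body
    Plethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the complexity of respiratory dynamics
    recorded by whole-body plethysmography. Extracts inter-breath interval
    (IBI) and respiratory volume (RV) time series from continuous pressure
    signals, computes nonlinear variability indices (sample entropy,
    cross-sample entropy, detrended fluctuation analysis scaling exponents,
    coefficients of variation), and compares experimental groups with
    one-way ANOVA/Bonferroni or Kruskal-Wallis/Dunn procedures. Includes a
    synthetic plethysmography generator with exact fractional Gaussian
    noise ground truth so every stage of the pipeline can be validated
    against known complexity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
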