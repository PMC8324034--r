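Package: xylemvc
Title: Xylem Vulnerability Curves and Stem Anatomical Drivers of Embolism Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying xylem embolism resistance from centrifuge
    (Cavitron) vulnerability curves and relating it to stem anatomy.
    Constructs percent-loss-of-conductivity curves, fits the sigmoid
    vulnerability model and derives P12/P50/P88, computes the standard wood
    anatomical trait set from raw microscopy measurements (hydraulically
    weighted vessel diameter, vessel implosion resistance, vessel grouping
    index, lignified area fraction, pit membrane thickness and allies), and
    runs the full inference chain: one-way ANOVA with Newman-Keuls post hoc
    letters, Pearson correlation, variance-inflation-factor screening,
    backward AIC model selection, robust iteratively reweighted least
    squares, and Lindeman-Merenda-Gold relative importance decomposition.
    Includes a seeded generator of synthetic Cavitron experiments and
    copula-linked trait tables so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car,
    optparse
Config/testthat/edition: 3
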