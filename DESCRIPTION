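Package: thermopartition
Title: Energy Partition Analysis of Growing Pigs from Indirect Calorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-animal energy-partition studies of growing pigs
    housed in open-circuit respiration chambers at gradient ambient
    temperatures. Converts chamber gas-concentration logs into daily oxygen,
    carbon-dioxide and methane exchange, computes heat production by the
    Brouwer equation, assembles the complete nitrogen and energy ledger
    (gross, digestible, metabolizable and net energy; retained energy and its
    protein/lipid partition; fasting heat production) on the metabolic
    bodyweight basis, fits quadratic bodyweight-by-temperature response
    surfaces by Gauss-Newton least squares, runs the treatment statistics
    used in such trials (one-way ANOVA, Tukey compact letters, orthogonal
    polynomial contrasts on unequally spaced temperatures), and screens
    plasma metabolite feature tables with Pareto scaling and a fold-change /
    coefficient-of-variation / p-value selection rule. A synthetic trial
    generator with known ground truth makes every stage testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
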