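Package: feralsim
Title: Hybrid Classification, Relative Survival and Eco-Genetic Simulation
    for Farmed-Escapee Atlantic Salmon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the fate of farmed-escapee Atlantic salmon
    offspring in the wild. Simulates multi-river parr surveys genotyped at a
    farm/wild-discriminating SNP panel (with Genepop import/export), assigns
    individuals to six genetic classes (wild, feral, F1, F2, and the two
    backcrosses) with a genotype-frequency-class Bayes classifier, estimates
    class-specific relative survival from within-cohort changes in class
    composition across rivers, and projects long-term consequences of escapee
    invasion with an annual-step individual-based eco-genetic population model
    (polygenic stage-specific survival, sex-specific reproduction with escapee
    spawning discounts, Beverton-Holt recruitment, pulsed invasion scenarios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
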