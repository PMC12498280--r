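Package: nurturekit
Title: Family-Based Estimation of Direct and Indirect Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying genetic nurture in nuclear families. Simulates
    cohorts of phased genotypes with assortative mating, Mendelian
    transmission and nurture-mediated phenotypes; imputes missing parental
    genotypes by conditional expectation under Mendelian inheritance,
    including a sibling identity-by-descent hidden Markov model; scores and
    standardizes polygenic risk scores; and jointly estimates direct and
    indirect genetic effects with ratio, variance-partition and contrast
    statistics. Also provides variant-level quality-control filters,
    KING-robust kinship estimation, greedy relatedness pruning and a
    principal-component Euclidean-distance ancestry gate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
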