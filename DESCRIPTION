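Package: gpresel
Title: Genomic Prediction with Preselected Sequence Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for studying genomic prediction
    when dense sequence variants are preselected from a genome-wide
    association study. Provides de-regression of estimated breeding values
    into pseudo-phenotypes, Yang-style genomic relationship matrices with
    complementary-set construction under linkage-disequilibrium exclusion
    rules, average-information REML for one- and two-component variance
    models, mixed-linear-model association scans with fixed variance
    components, conditional-and-joint forward variant selection, GBLUP
    training with back-solved marker effects, and validation accuracy and
    bias metrics. A gene-dropping simulator generates half-sib structured
    populations with LD-structured dense genotypes and progeny-based
    reliabilities so the whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
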