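Package: cadhesion
Title: Cadherin Expression Energy and Relative Adhesion in the Developing Mouse CNS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify in situ hybridization expression energy of
    classical cadherins across the ontology of the developing mouse central
    nervous system and to convert expression levels into modeled cell-cell
    adhesion. Implements the expression-energy summary statistic and
    structure-unionize aggregation, an ontology of neuromeric segments,
    plates, subpallial strata and cortical areas/layers, a biophysical model
    of homophilic cadherin trans-dimer equilibrium yielding the work of
    separation between two cells and relative adhesion normalized to an
    N-cadherin reference, Pearson correlation and plate-ratio analyses of
    expression profiles, a comparison of ISH against single-cell RNA-seq
    cluster means, and a seeded synthetic-data generator producing expression
    tables with controlled between-gene correlations and planted
    fold-differences so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
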