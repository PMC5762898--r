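Package: evenpanel
Title: Evenness-Stratified Synthetic Microbial Community Panels and Their
    Diversity Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and analysis toolkit for synthetic microbial ecosystems
    of fixed richness and varying initial evenness. Generates
    Pielou-evenness-stratified community panels from an in-silico candidate
    pool, simulates serial-transfer dynamics under generalized
    Lotka-Volterra competition, and emulates the two measurement modalities
    of such experiments: flow-cytometry event tables (four channels plus
    debris) and amplicon-style phylotype count tables with detection bias.
    Implements flow-cytometric fingerprinting (polygon gating,
    kernel-density phenotype fingerprints, Hill-number phenotypic
    diversity), taxonomic alpha diversity (Shannon, Simpson, Pielou,
    Fisher's alpha, Hill numbers, analytic rarefaction), and the
    comparative statistics layer: Bray-Curtis PERMANOVA, principal
    coordinate analysis, group dispersion tests, multiple factor analysis
    with category v-tests, permutation trend tests, and
    phenotypic-taxonomic diversity correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
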