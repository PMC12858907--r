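Package: commfba
Title: Community Flux Balance Analysis for Synthetic Microbial Consortium Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling of microbial communities.
    Builds multi-strain community models from single-strain genome-scale
    metabolic models by joining them through a shared extracellular
    metabolite pool, solves community flux balance analysis (FBA) and
    parsimonious FBA under four community objective scenarios, screens all
    strain combinations across media series with one, two, or four carbon
    sources, simulates growth on a finite nutrient pool, extracts directed
    cross-feeding networks from flux solutions, and quantifies the
    contribution of non-competing donor ("potentiator") strains via the
    Potentiator Contribution Index. Ships a seeded toy-model generator with
    designed degrader/helper/potentiator roles so the whole pipeline is
    testable without external model downloads, plus readers and writers for
    SBML Level 3 (fbc), a minimal JSON model dialect, media TSV, and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    xml2,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
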