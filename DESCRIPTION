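Package: fluxcut
Title: Elementary Modes, Minimal Cut Sets and Knockout Flux States for
    Plant Pigment Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural and functional analysis of metabolic subnetworks,
    built around the anthocyanin biosynthetic pathway of Arabidopsis.
    Reads constraint-based models from SBML or a tab-delimited
    reaction/metabolite dialect, extracts coherent subnetworks from a
    larger network by iterative traceback around seed pathways, enumerates
    elementary flux modes exactly with integer arithmetic, computes
    minimal cut sets for objective reactions by hitting-set dualization,
    scores reactions by participation and fragility coefficients, and
    quantifies the impact of each cut set on other products by comparing
    deterministic flux states against a constrained reference state.
    Includes generators for synthetic benchmark networks with known
    elementary-mode and cut-set answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
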