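Package: boolcube
Title: Conversion of Boolean Regulatory Networks into Continuous ODE Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts qualitative Boolean models of gene regulation into
    systems of ordinary differential equations by multilinear interpolation
    of the Boolean update functions (BooleCube) and composition with
    sigmoidal Hill kinetics (HillCube, normalized HillCube). Boolean models
    can be entered as text equations, imported from GraphML interaction
    graphs or hypergraphs, or generated at random. The package provides
    synchronous Boolean analysis (steady states, state-transition graph,
    attractors), expansion of single-cell models into linear rows of coupled
    compartments with secreted factors, numerical integration and stable
    steady-state discovery with basin labelling, an ensemble
    pattern-maintenance screen for model selection, and export to SBML
    (rate-rule form) and plain ODE script files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
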