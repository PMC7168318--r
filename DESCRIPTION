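Package: robustfba
Title: Robustness Analysis of Genome-Scale Metabolic Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models
    focused on metabolic robustness, motivated by photoautotroph (diatom)
    metabolism. Implements parsimonious flux balance analysis with a
    lexicographic biomass / Manhattan-norm objective, quadratic minimization
    of metabolic adjustment (MOMA), model quality controls (energy
    generation from nothing, metabolite leak tests), single reaction and
    single gene deletion scans with robust / intermediate / essential
    classification and compensatory-response accounting, optional divergent
    allelic-variant augmentation of gene-protein-reaction rules, local
    one-at-a-time and Morris elementary-effects sensitivity analysis of
    biochemical composition parameters, and directed bipartite
    metabolite-reaction network centrality metrics. Includes a biomass
    reaction builder driven by a 69-parameter biochemical composition table,
    SBML (Level 3 + fbc) and JSON model input and output, and a
    deterministic synthetic model generator with a brute-force deletion
    oracle for validation. Linear programs are solved by a bundled
    bounded-variable primal simplex; quadratic programs by 'quadprog'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    lhs,
    quadprog,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
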