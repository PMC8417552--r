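Package: cliquepred
Title: Structure-Based Prediction of Missense Mutation Effects from
    Residue Packing, Depth and Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the functional consequence (neutral versus
    destabilizing) of missense mutations in proteins.  Builds a
    depth-stratified multi-body statistical potential over residue
    cliques enumerated on a side-chain contact graph, computes residue
    depth by explicit lattice solvation, scores positional conservation
    as Shannon entropy over a multiple sequence alignment, and routes
    depth-dependent amino-acid substitution likelihood matrices by
    burial zone.  The three terms are combined in a trained linear
    classifier with grid-search weight optimisation, confusion-matrix
    and Matthews-correlation evaluation, depth-zone stratified accuracy
    analysis, and best-method-per-category meta-prediction.  Includes
    deterministic synthetic generators for structures, structure
    corpora, alignments, substitution matrices and labeled mutation
    sets so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
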