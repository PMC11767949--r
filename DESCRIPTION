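Package: chirind
Title: Relative Chirality Indices and Chirality-Sensitive QSAR Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes relative chirality indices (RCIs), per-stereocenter
    descriptors that distinguish R and S isomers by combining the four
    CIP-ranked substituent fragments of a chiral carbon, each weighted by a
    topological index of the fragment graph (Balaban J, Kier-Hall chi and
    kappa, Zagreb, overall connectivity, Basak information content, and
    triplet indices).  Includes a SMILES parser for the organic subset with
    tetrahedral stereo perception, CIP substituent ranking, a registry of
    weighting schemes, and a chirality-sensitive QSAR pipeline (ln(x+1)
    standardization, correlation-matrix PCA with Kaiser retention, stepwise
    regression on component scores, per-component descriptor selection, and
    k-fold cross-validation) exposed as a classed model object.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
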