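Package: retroedits
Title: Single-Step Retrosynthesis by Autoregressive Molecular Graph Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end semi-template framework for single-step
    retrosynthesis prediction.  Atom-mapped reactions are diffed into
    ground-truth sequences of graph edits (delete bond, change bond,
    change atom, attach leaving group, terminate); a directed
    message-passing neural network encoder combined with an
    autoregressive edit decoder is trained by teacher forcing to
    reproduce those sequences; beam-search decoding turns a product
    molecule into ranked reactant candidates.  Includes a molecular
    graph data model with SMILES input/output and canonicalization, a
    deterministic edit-application engine, a seedable generator of
    synthetic atom-mapped reactions with known edit sequences,
    Tanimoto-based data splitting, and the standard top-k exact-match,
    maximum-fragment and prediction-diversity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
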