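Package: crossfuseGO
Title: Cross-Fusion of PPI Networks and Protein Attributes for GO Term Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-label protein function (Gene Ontology term) prediction by
    cross-fusing a weighted protein-protein interaction network with binary
    protein attributes (Pfam domains and subcellular locations) through
    multi-head self-attention. A self-supervised encoder-decoder is
    pre-trained to reconstruct both feature sources, then fine-tuned with an
    asymmetric multi-label loss under a freeze/unfreeze schedule. Includes
    CAFA-style data preparation (evidence-code filtering, temporal
    train/validation/test splits, GO-term selection rules), the full
    evaluation suite (micro/macro AUPR, top-3 F1, exact-match accuracy,
    Fmax, Davies-Bouldin index), and a synthetic planted-module data
    generator so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    yaml
Config/testthat/edition: 3
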