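Package: bindspec
Title: Transcription-Factor Binding Specificity from Protein-DNA Complex Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the DNA-binding specificity of a transcription factor from a
    single protein-DNA co-crystal structure. Base pairs of the bound duplex are
    mutated in silico by rigid-body template replacement, every mutant complex is
    scored with a trainable all-atom distance-dependent knowledge-based potential,
    mutants within an energy-change flexibility criterion are summarized as a
    position frequency matrix (PFM), and candidate binding sequences are ranked by
    PFM score. Includes PDB reading and writing with double-stranded DNA detection
    and protein-contact annotation, potential training from complex collections,
    evaluation metrics (Psi divergence between PFMs, ROC/AUC, sensitivity and
    specificity), and a synthetic B-DNA fixture generator so the whole pipeline is
    testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
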