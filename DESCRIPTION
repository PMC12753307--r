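Package: mogedn
Title: Multi-Omics Graph Encoder-Decoder Networks for Cancer Subtype
    Classification with Missing-Modality Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements MOGEDN, a framework for cancer subtype
    classification from multi-omics data (mRNA expression, DNA
    methylation, miRNA expression) that remains usable when an entire
    omics modality is missing. Per-modality graph convolutional encoders
    operate on cosine-similarity patient graphs; a shared multi-head
    decoder reconstructs the latent representation of a missing modality
    from the remaining ones; per-modality classifier heads and a view
    correlation discovery network (VCDN) fuse predictions across omics.
    Training follows a three-phase curriculum (supervised encoder
    pretraining with focal loss, decoder pretraining on latent
    reconstruction, joint training under simulated modality masking)
    followed by per-cohort finetuning. Also provides input-times-gradient
    attribution for shared and tumor-specific biomarker ranking, a
    seeded synthetic multi-omics cohort generator, and TSV/CSV readers
    and writers for sample-by-feature matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
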