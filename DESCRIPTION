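Package: mmcdr
Title: Multimodal Contrastive Learning for Cancer Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary drug sensitivity (sensitive/resistant) of cancer
    cell lines from multi-omics profiles (gene expression, copy number
    variation), cell morphology images, and drug structures. Cell lines are
    embedded by linear omics encoders fused with per-sample softmax attention
    and a small convolutional image encoder; the omics and image views are
    aligned with a symmetric InfoNCE contrastive objective. Drugs are encoded
    from SMILES-derived molecular graphs (75-dimensional ConvMol-style atom
    features) with a two-layer graph convolutional network and global max
    pooling. An MLP head scores cell line-drug pairs; training combines
    cross-entropy and contrastive losses and is evaluated by stratified
    k-fold cross-validation with AUROC/AUPR. Includes a synthetic-data
    generator with planted cross-modal alignment and response signal, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    EBImage,
    jsonlite,
    png,
    optparse,
    stats,
    utils,
    tools,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
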