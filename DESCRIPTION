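Package: methFusion
Title: Dual-Scale Transformer with Adversarial Training for DNA Methylation
    Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts DNA methylation sites (4mC, 5mC, 5hmC, 6mA) from
    fixed-length sequence windows using a dual-scale k-mer language model:
    sequences are tokenized into overlapping 3-mers and 6-mers, each scale is
    encoded by a small transformer, and the two pooled representations are
    combined through a dimension-wise sigmoid fusion gate before a fully
    connected classification head. Training supports fast-gradient-method
    (FGM) adversarial perturbation of the token embeddings, early stopping,
    and fine-tuning for transfer between methylation sequence contexts (CpG,
    CHG, CHH). Includes attention-based interpretation (per-base importance
    tracks, motif window extraction, position weight matrices, MEME-format
    export), genome-scale scanning of candidate cytosines with bedGraph/BED
    output, evaluation metrics (ACC, MCC, SN, SP, ROC/AUC, PR/AP,
    cross-condition grids), and a synthetic planted-motif data generator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
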