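Package: modsite
Title: Sequence-Based Prediction of Post-Translational Modification Sites
    Using Known-Site Tokens
Version: 0.1.0
Authors@R:
    person("modsite", "developers", email = "modsite@example.org",
           role = c("aut", "cre"))
Description: Predicts post-translational modification (PTM) sites from protein
    sequence with a small convolutional neural network over a learned word
    embedding, in which residues already known to carry the PTM are encoded as
    extra amino-acid tokens ("@"/"&"). Provides dataset construction with
    negative balancing, identity-aware train/validation/test splitting and
    Monte Carlo cross-validation; model training, persistence and prediction;
    threshold-free evaluation (AUC/AUPRC) with paired comparison of labeled
    versus unlabeled models; integrated-gradients interpretability with
    position-summed attributions, K-means clustering and sequence-logo
    frequency matrices; proximity analysis of known PTMs around candidate
    sites; a synthetic proteome generator with planted motifs and PTM
    crosstalk; and a command-line interface including a train-your-own-model
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
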