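Package: molemcl
Title: Multi-Level Contrastive Learning for Molecular Graph Pre-Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pre-training of graph neural network encoders on
    unlabeled molecules, combining attribute-masking contrastive learning
    (node-attribute reconstruction plus a graph-level NT-Xent loss between a
    molecule and its masked view) with a gradient-compensated encoder
    parameter-perturbation contrastive module that perturbs encoder weights
    along the contrastive-loss gradient to form a second positive view.
    Includes molecular featurization from SMILES, Bemis-Murcko scaffold
    splitting, multi-task fine-tuning with missing-label masking and ROC-AUC
    evaluation, and embedding-based molecular retrieval with Tanimoto
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    pROC,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
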