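Package: mirtarnet
Title: miRNA-mRNA Interaction Prediction from Sequence and Graph Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microRNA-mRNA interactions by fusing two complementary
    views of each candidate pair: k-mer sequence embeddings pretrained with a
    skip-gram (FastText-style) objective and fed through a CNN-BiLSTM encoder
    with a cross-sequence mutual attention mechanism, and GraRep node
    embeddings of the bipartite interaction graph obtained by factorising
    log-transformed powers of the random-walk transition matrix. A
    backpropagation fusion network combines both views into an interaction
    probability. Includes negative sampling, stratified cross-validation with
    leak-free per-fold graph embeddings, the usual binary classification
    metric suite (ACC, F1, AUC, AUPR, MCC, SEN, PPV, TNR), and a seeded
    synthetic-data generator that plants a seed-complementarity signal so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
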