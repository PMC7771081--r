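Package: threadr
Title: Template-Based Protein Threading with a Residual Convolutional
    Alignment Scorer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A template-based protein structure prediction (threading)
    engine. Pairwise template-query feature tensors are assembled from
    sequence profiles, observed and predicted sequential structural
    features, and eigenvector embeddings of residue-residue contact maps;
    a fully-convolutional residual network scores every residue-residue
    pair with an aligning probability, and a Maximum Accuracy dynamic
    program turns the probability matrix into a local template-query
    alignment whose optimal score ranks templates in a library. Includes
    TM-score-weighted cross-entropy training with AdamW, structure
    similarity metrics (Kabsch superposition, TM-score, GDT), readers and
    writers for FASTA, A3M, PDB, PIR and tabular formats, and a synthetic
    template-query pair generator with known ground-truth alignments for
    desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
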