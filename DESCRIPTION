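Package: interologr
Title: Interolog-Based Prediction of Protein-Protein Interaction Networks
    from Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-protein interaction networks for a species
    with no experimental interactome by transferring interactions from a
    reference human network through sequence homology (interolog mapping).
    Resolves a best human homolog per transcript from BLAST, EggNOG model
    and PFAM domain meta-alignment evidence; computes a 19-feature vector
    per candidate transcript pair (interactome path length, domain-domain
    interaction score, GO normalized term overlap, alignment measures);
    classifies pairs with a downsampled random forest evaluated on
    out-of-bag votes; and exports the predicted networks as a property
    graph with pathway search and expression overlays. Includes a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    randomForest,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
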