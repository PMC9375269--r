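Package: sirnaboundary
Title: Potency-Boundary Construction and Efficacy Prediction for 19-nt siRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates potent from ineffective 19-nt siRNAs by constructing a
    boundary from local sequence similarity rather than a global decision
    rule. Sequences are encoded as composite multinucleotide-frequency and
    positional one-hot features (31 combinations); two neighbour structures
    (nearest-neighbour mini-groups and farthest-point-seeded mini-clusters)
    yield binarized group-purity features over a ladder of artificial
    efficacy cut-offs; an iterative removal procedure transfers recognisably
    ineffective test siRNAs into the training pool, and surviving test siRNAs
    are called potent. Knockdown efficacy is predicted by mini-group
    averaging over same-class training neighbours. Includes a seeded
    synthetic-data generator with planted motif families, evaluation metrics
    (sensitivity, specificity, Pearson correlation), and a reproducible
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
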