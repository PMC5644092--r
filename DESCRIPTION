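Package: readtaxr
Title: Lineage-Level Taxonomic Assignment of Metatranscriptomic Reads
Version: 0.1.0
Authors@R: person("readtaxr", "maintainers", email = "maintainers@readtaxr.org",
    role = c("aut", "cre"))
Description: Assigns short metatranscriptomic reads from eukaryotic
    microorganisms to broad taxonomic lineages by protein-similarity search
    against a curated reference database, and filters unreliable assignments
    with a five-feature binary logistic-regression model built from the best
    hit (BH) and the next lineage hit (NLH) of each read. Includes parsing of
    tabular (m8 / BLAST outfmt 6) similarity hits, a self-contained
    reduced-alphabet translated search for testing and demos, per-sample count
    matrices with total-count normalization and composition plots, a full
    training and evaluation toolkit (Monte Carlo cross-validation, ROC/AUC,
    cutoff selection, E-value-cutoff baseline, random-read rejection), and a
    synthetic-data generator producing reference databases, labeled reads and
    feature-level datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
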