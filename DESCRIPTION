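Package: funscreen
Title: Structure-Free Virtual Screening with Protein Function Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based protein-ligand binder classification for virtual
    screening. Proteins are represented solely by fixed-length molecular-function
    score vectors (DeepFRI-style, 489 classes by default); small molecules by a
    directed bond-level message-passing graph encoder. The two representations
    are fused (addition or concatenation) and passed through feed-forward layers
    for binary active/inactive classification. Includes activity-record curation
    with a 50 micromolar labeling cutoff, decoy augmentation with assumed
    negatives, Bemis-Murcko scaffold-balanced splitting, ensemble training,
    enrichment-factor and threshold-confusion evaluation, a sequence-identity x
    Tanimoto train/test leakage filter, and a planted-rule synthetic world
    generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
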