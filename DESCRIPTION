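Package: saflex
Title: Protein Flexibility from Structural-Alphabet Conformational Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes and predicts protein backbone flexibility through
    structural alphabets. Backbone conformations are encoded as strings over
    four local-structure alphabets (3- and 8-class secondary structure, the
    16-letter Protein Blocks alphabet assigned by dihedral RMSD, and a
    trainable 28-letter Cartesian fragment alphabet). Per-residue
    conformational entropy is computed from letter frequencies across
    conformational ensembles (e.g. decoy sets) or from per-residue class
    distributions emitted by a dual-layer sequence-profile predictor, and is
    used as a flexibility indicator: entropy is correlated with
    crystallographic B-factors, and residues are classified as flexible or
    rigid by an entropy threshold with ROC-based evaluation. Includes a
    synthetic-data generator producing perturbed backbone ensembles with
    known per-position letter distributions, matched B-factor profiles and
    sequence profiles carrying a learnable local-structure signal.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
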