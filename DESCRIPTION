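Package: dnajtype
Title: Type Classification of DnaJ/HSP40 Co-Chaperones from Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns J-proteins (DnaJ/HSP40 co-chaperones) to one of the four
    structural types (I-IV) from amino-acid sequence. Sequences are encoded as
    hybrid feature vectors combining split amino acid composition over
    N-terminal, central and C-terminal segments, pseudo amino acid composition
    built from lagged autocovariances of twelve physicochemical property
    profiles, and autocovariances of sigmoid-normalised PSI-BLAST
    position-specific scoring matrices. Features are ranked by symmetric
    uncertainty with the class and pruned by incremental feature selection.
    The severe class imbalance typical of J-protein data (type III dominates)
    is handled by SMOTE oversampling of the rarest type and 20-way
    undersampling of the majority type, training twenty heterogeneous
    one-versus-rest subclassifiers combined by majority vote with
    nearest-centroid tie-breaking. Includes per-class stratified
    cross-validation, sensitivity-based evaluation, and a synthetic benchmark
    generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    e1071,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
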