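Package: allerknn
Title: Alignment-Free Allergen Prediction from Physicochemical Sequence
    Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts protein allergenicity without sequence alignment.
    Protein sequences are encoded residue-by-residue with the three
    Hellberg z-descriptors (hydrophobicity, size, polarity) and converted
    into uniform 45-component vectors by auto- and cross-covariance (ACC)
    transformation with lags 1..5. Classification is by k-nearest
    neighbours (default k = 3) with a decision threshold of 0.5 and
    assignment of the most probable route of exposure (food, inhalant,
    toxin) from the routes of the nearest allergen neighbours. Includes
    labelled-dataset input/output, mirror non-allergen set construction by
    similarity screening, a seeded synthetic sequence generator with
    class-dependent composition bias, stratified cross-validation, a k
    scan, cross-comparative route analysis, baseline classifiers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    rpart,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
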