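Package: antioxvote
Title: Antioxidant Protein Classification by Vote-Stacked Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies antioxidant proteins from sequence alone. Protein
    sequences are encoded as g-gap dipeptide compositions (g = 0..9) and as
    reduced amino-acid n-peptide compositions over five physicochemical
    cluster profiles; features are ranked by one-way ANOVA F-value and pruned
    by incremental feature selection; per-encoding radial-basis support vector
    machines are trained, filtered by test-set sensitivity, and their signed
    predictions stacked into a vote vector that a final support vector machine
    classifies. Includes jackknife and k-fold evaluation with sensitivity,
    specificity, accuracy and Matthews correlation, a synthetic sequence
    generator with plantable compositional signal, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
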