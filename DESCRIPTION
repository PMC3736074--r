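Package: healthtopics
Title: Topic Classification of Online Health Community Messages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based topic identification for user-generated messages in
    online health communities. Builds bag-of-words n-gram features (n <= 3),
    medical domain-term features filtered by UMLS-style semantic types, and
    sentiment features drawn from a SentiWordNet-format lexicon; assembles the
    incremental feature sets FS1-FS4 with information-gain feature reduction;
    and evaluates Bernoulli naive Bayes, a gain-ratio decision tree, and a
    polynomial-kernel support vector machine under stratified tenfold
    cross-validation with paired t-tests. Includes a synthetic labeled-corpus
    generator with a matching Bayes-optimal oracle so the whole pipeline is
    testable without licensed lexical resources, plus a command-line interface
    for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
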