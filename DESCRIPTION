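Package: prerob
Title: Detecting Reporting of Risk-of-Bias Items in Preclinical Full Texts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Text-classification toolkit for detecting whether full-text
    preclinical (animal) research publications report five risk-of-bias
    items: random allocation, blinded assessment of outcome, conflict of
    interests, compliance with animal welfare regulations, and animal
    exclusions. Provides text cleaning and tokenization, corpus splitting,
    TF-IDF and embedding-based document representations, paragraph-vector
    document embeddings, classic baselines (support vector machine,
    logistic regression, random forest), neural classifiers implemented
    natively (one-layer convolutional network, bidirectional recurrent
    network with attention, hierarchical attention network), two strategies
    for applying 512-token-limited contextual encoders to ~5000-token
    documents (document chunk pooling and similarity-based sentence
    extraction), confusion-matrix metrics with exact McNemar comparison,
    attention-based evidence extraction, and a synthetic-corpus generator
    with planted evidence phrases for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
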