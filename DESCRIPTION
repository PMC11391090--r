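Package: deprscreen
Title: Hierarchical Transformer Screening of Depression Risk in Social-Media Timelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: User-level depression-risk detection from timelines of short
    social-media posts. Implements a hierarchical transformer network (a
    word-level transformer with [CLS] pooling per post, a chronological
    post-level transformer, an attention-LSTM aggregator and a sigmoid
    classification head), a retrieval-based lexicon post-sampling strategy,
    flat concatenated-text baseline encoders (CNN, LSTM, GRU, BiLSTM, BiGRU,
    optionally with additive attention, and a hierarchical convolutional
    network), a preprocessing pipeline for noisy CJK microblog text, a
    synthetic-corpus generator with controllable lexical signal, and
    LIWC-style linguistic and behavioural group comparison. All encoders are
    trained with a small built-in reverse-mode automatic-differentiation
    engine, so the package has no deep-learning framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
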