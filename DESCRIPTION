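Package: dreamlsa
Title: Latent Semantic Similarity Between Psychoactive-Substance and Dream Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A comparative-phenomenology text-mining pipeline that quantifies
    the semantic similarity between free-text reports of psychoactive-substance
    experiences and dream reports of high and low lucidity. Documents (one per
    substance, one per dream-lucidity class) are built from censored,
    lemmatized report collections, weighted by tf-idf with a document-frequency
    retention band, reduced by truncated singular value decomposition (latent
    semantic analysis), and compared by Pearson correlation of the
    rank-reduced columns. The statistical layer turns similarity vectors into
    substance rankings, per-category summaries, a two-factor analysis of
    variance, pairwise nonparametric category tests, lucidity-difference
    rankings, cross-similarity predictions (Spearman), term-rank tables behind
    word clouds, and a retained-rank stability analysis. A seeded topic-model
    corpus generator with exact ground-truth similarities makes every stage
    testable without access to the original web corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
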