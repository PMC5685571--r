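Package: swbprofiler
Title: Subjective Well-Being Profiles from Social-Media Status Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a subjective well-being (SWB) profile for social-media
    users from their short status-update texts. Statuses are cleaned
    (emoticon-to-word conversion, hyperlink/digit/punctuation removal) and
    scored with a valence lexicon to give per-user affect intensity and
    frequency features; closed-vocabulary category counts and topic scores
    from a truncated word-topic table (both the word-count and the
    probability-weighted variant) complete the feature matrix. Elastic-net
    regression reduces the topic space, and a random forest predicts
    satisfaction with life (SWL) with out-of-bag and held-out evaluation,
    a jittered-median baseline, and permutation variable importance. The
    predicted SWL plus affect features form the SWB profile, whose
    predictive validity is checked against CES-D depression scores, and
    activity-conditioned sentiment z-scores with Cohen's kappa inter-rater
    agreement complete the analysis. A synthetic-corpus generator with
    planted ground truth makes every stage testable without access to any
    private social-media data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    ranger,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr,
    optparse
Config/testthat/edition: 3
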