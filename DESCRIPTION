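Package: plebeian
Title: Democratic Content Moderation and Sentiment Distribution Analytics
Version: 0.1.0
Authors@R:
    person("Plebeian", "Maintainers", email = "maintainers@plebeian.example", role = c("aut", "cre"))
Description: Tools for infodemiology at desk scale: a deterministic text-cleaning
    and lexicon-based polarity pipeline for social-media corpora, histogram and
    kernel-density summaries of bimodal sentiment distributions (negative and
    positive mode locations and a log-ratio skewness), keyword-taxonomy
    filtering with per-category comparisons, a two-phase democratic moderation
    engine (a popularity-gated Flag Phase and a randomly empanelled Jury Phase)
    with a one-byte incremental thread-state encoding, Condorcet jury-accuracy
    calculations, and a seeded synthetic corpus generator so the whole pipeline
    is exercisable without platform API access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
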