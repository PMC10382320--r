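Package: dartmap
Title: Pathway Activity and Connectivity Scoring for Compound Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering small-molecule compounds that modulate a
    transcriptional pathway. Builds directional gene signatures (up/down tag
    sets), scores per-sample pathway activity with a relevance-network
    denoising estimator (DART: Pearson correlation network over signature
    genes, Fisher-z edge significance, pruning of prior-inconsistent edges,
    degree-weighted sign-directed activity score), scores perturbational
    instances against a signature with the Kolmogorov-Smirnov tag-set
    connectivity statistic, and prioritises compounds by ranking and
    intersecting the two branches. Includes a synthetic perturbational-data
    generator so the full screen can be exercised and validated without any
    external download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
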