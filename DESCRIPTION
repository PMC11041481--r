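Package: rxwhyqa
Title: Build, Analyze and Evaluate Multi-Answer Drug-Reason Extractive QA Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts drug-reason relation annotations on clinical notes (BRAT
    standoff dialect) into a SQuAD-2.0-style extractive question-answering
    dataset with unanswerable, multi-answer and multi-drug questions; computes
    corpus analytics (answer-count distributions, term and pair frequencies,
    drug-reason sentence distances, contextual trigger patterns, on/off-label
    screening); generates seeded synthetic corpora with planted relation
    structure; drives any single-answer extractive QA model through an
    incremental answer-masking loop to surface multiple answers; and scores
    M-to-N answer sets with a weighted token-overlap precision/recall/F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stringr,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
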