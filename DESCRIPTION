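Package: trialmatchr
Title: Patient-to-Trial Matching with Pluggable Language-Model Backends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for matching free-text patient notes to
    clinical trials: keyword-based hybrid retrieval with reciprocal rank
    fusion over lexical (Okapi BM25) and semantic (pluggable embedder)
    rankings; criterion-level eligibility classification with natural-language
    explanations and evidence sentence locations produced by a pluggable
    language-model backend; and trial-level score aggregation for ranking
    candidate trials and excluding ineligible ones. Includes graded-relevance
    ranking metrics (Recall@k, NDCG@k, graded P@k, AUROC), TREC qrels/run
    readers and writers, a synthetic patient-cohort simulator with
    criterion-level ground truth, and a deterministic mock backend so the
    whole pipeline runs and is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
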