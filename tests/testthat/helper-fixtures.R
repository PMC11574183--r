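# Shared fixtures: a small simulated cohort memoised across test files, plus
# independently coded brute-force oracles for BM25, rank fusion, and NDCG.

shared_cohort_env <- new.env(parent = emptyenv())

# Small cohort reused by unit tests (6 patients x 60 trials, fixed seed).
shared_cohort <- function() {
  if (is.null(shared_cohort_env$cohort)) {
    shared_cohort_env$cohort <- generate_cohort(n_patients = 6, n_trials = 60,
                                                seed = 7)
  }
  shared_cohort_env$cohort
}

tiny_corpus <- function() {
  tibble::tibble(
    trial_id = c("NCT00000003", "NCT00000001", "NCT00000002"),
    title = c("Insulin therapy in diabetes", "Aspirin for headache",
              "Diabetes prevention with diet"),
    conditions = list("diabetes", "headache", "diabetes"),
    interventions = list("insulin", "aspirin", "diet"),
    brief_summary = c("A study of insulin dosing in diabetes.",
                      "Aspirin versus placebo.",
                      "Dietary intervention for diabetes."),
    inclusion_criteria = list(c("Diagnosis of diabetes.", "Age over 18."),
                              "Recurrent headache.",
                              "At risk of diabetes."),
    exclusion_criteria = list("Pregnancy.", character(), "Use of insulin.")
  )
}

# Backend built from a fixed mapping of request type to raw response text.
scripted_backend <- function(responses) {
  llm_backend(function(request) {
    out <- responses[[request$type]]
    if (is.function(out)) out <- out(request)
    out
  }, model_id = "scripted")
}

# Wrap a backend so that calls are counted (for cache / call-count tests).
counting_backend <- function(backend) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  wrapped <- llm_backend(function(request) {
    calls$n <- calls$n + 1L
    backend$handler(request)
  }, model_id = backend$model_id)
  list(backend = wrapped, calls = calls)
}

# --- independent oracles ----------------------------------------------------

# Textbook Okapi BM25 computed from scratch per (query, document), without
# any indexing machinery.
oracle_bm25_score <- function(query, doc_texts, k1 = 1.5, b = 0.75) {
  tok <- function(x) {
    t <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
    t[nzchar(t)]
  }
  docs <- lapply(doc_texts, tok)
  qs <- unique(tok(query))
  N <- length(docs)
  avgdl <- mean(vapply(docs, length, integer(1)))
  vapply(seq_len(N), function(j) {
    s <- 0
    for (term in qs) {
      df <- sum(vapply(docs, function(d) term %in% d, logical(1)))
      if (df == 0) next
      tf <- sum(docs[[j]] == term)
      idf <- log(1 + (N - df + 0.5) / (df + 0.5))
      s <- s + idf * tf * (k1 + 1) /
        (tf + k1 * (1 - b + b * length(docs[[j]]) / avgdl))
    }
    s
  }, numeric(1))
}

# Brute-force double sum over retrievers and keywords for one trial.
oracle_fused_score <- function(trial, rank_lookup, retrievers, n_keywords, C) {
  s <- 0
  for (ret in retrievers) {
    for (i in seq_len(n_keywords)) {
      r <- rank_lookup(ret, i, trial)
      if (!is.na(r)) s <- s + 1 / (i * (r + C))
    }
  }
  s
}

# Closed-form NDCG from first principles.
oracle_ndcg <- function(grades_in_rank_order, all_grades, k) {
  dcg <- function(g) sum(head(g, k) / log2(seq_along(head(g, k)) + 1))
  idcg <- dcg(sort(all_grades, decreasing = TRUE))
  if (idcg == 0) return(NA_real_)
  dcg(grades_in_rank_order) / idcg
}
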