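# First-stage retrieval: language-model keyword generation, per-keyword
# lexical (Okapi BM25) and semantic (pluggable embedder) rankings, and
# reciprocal-rank fusion with a 1/i importance decay across keywords.

tokenize <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Build an Okapi BM25 index over a trial corpus
#'
#' Each trial document is the concatenation of its title, conditions,
#' interventions, brief summary, and all criterion texts, lowercased and
#' tokenized on non-alphanumeric characters. Scoring uses the standard Okapi
#' term-frequency saturation with `k1 = 1.5`, `b = 0.75` by default and the
#' smoothed non-negative inverse document frequency
#' `log(1 + (N - df + 0.5) / (df + 0.5))`.
#'
#' @param corpus A trial-corpus tibble.
#' @param k1,b Okapi parameters.
#' @return A `bm25_index` object.
#' @export
bm25_index <- function(corpus, k1 = 1.5, b = 0.75) {
  corpus <- as_trial_corpus(corpus)
  assert_scalar_number(k1, "k1", min = 0)
  assert_scalar_number(b, "b", min = 0)
  docs <- tokenize(trial_document_text(corpus))
  tf <- lapply(docs, function(t) {
    if (length(t) == 0L) return(integer())
    tab <- table(t)
    setNames(as.integer(tab), names(tab))
  })
  doc_len <- vapply(docs, length, integer(1))
  all_terms <- unlist(lapply(tf, names), use.names = FALSE)
  df <- table(all_terms)
  structure(list(trial_id = corpus$trial_id, tf = tf, doc_len = doc_len,
                 avgdl = if (length(doc_len) > 0) mean(doc_len) else 0,
                 df = setNames(as.integer(df), names(df)),
                 n_docs = nrow(corpus), k1 = k1, b = b),
            class = "bm25_index")
}

#' Rank trials for one keyword with BM25
#'
#' Returns the trials with positive BM25 score for the (possibly multi-word)
#' query, sorted by descending score with ties broken by `trial_id`. A query
#' that tokenizes to nothing, or whose terms are absent from the corpus,
#' yields an empty ranking.
#'
#' @param query Keyword string.
#' @param index A [bm25_index()].
#' @return Tibble with `trial_id`, `rank` (1-based), `score`.
#' @export
bm25_rank <- function(query, index) {
  stopifnot(inherits(index, "bm25_index"))
  terms <- tokenize(query)[[1]]
  terms <- unique(terms[terms %in% names(index$df)])
  if (length(terms) == 0L || index$n_docs == 0L) {
    return(tibble(trial_id = character(), rank = integer(), score = numeric()))
  }
  idf <- log(1 + (index$n_docs - index$df[terms] + 0.5) / (index$df[terms] + 0.5))
  k1 <- index$k1; b <- index$b
  norm <- k1 * (1 - b + b * index$doc_len / index$avgdl)
  scores <- vapply(seq_len(index$n_docs), function(j) {
    tfj <- index$tf[[j]][terms]
    tfj[is.na(tfj)] <- 0
    sum(idf * tfj * (k1 + 1) / (tfj + norm[j]))
  }, numeric(1))
  keep <- which(scores > 0)
  if (length(keep) == 0L) {
    return(tibble(trial_id = character(), rank = integer(), score = numeric()))
  }
  ord <- keep[order(-scores[keep], index$trial_id[keep])]
  tibble(trial_id = index$trial_id[ord], rank = seq_along(ord),
         score = scores[ord])
}

#' Deterministic hashing text embedder
#'
#' A dependency-free stand-in for a dense biomedical text encoder: tokens are
#' hashed into `dim` signed buckets and the resulting count vector is
#' L2-normalised, so the inner product behaves like a cosine similarity over
#' hashed token overlap. Deterministic by construction; intended for offline
#' runs and tests. Any `function(character) -> matrix` with a fixed number of
#' columns can be supplied wherever an embedder is accepted.
#'
#' @param dim Number of hash buckets (embedding dimension).
#' @return An embedder function mapping a character vector to a
#'   `length(x) x dim` matrix.
#' @export
hash_embedder <- function(dim = 256L) {
  assert_scalar_number(dim, "dim", min = 2)
  dim <- as.integer(dim)
  function(x) {
    toks <- tokenize(x)
    emb <- matrix(0, nrow = length(x), ncol = dim)
    for (i in seq_along(toks)) {
      for (t in toks[[i]]) {
        h <- derive_seed(t, 7L)
        bucket <- (h %% dim) + 1L
        sign <- if ((h %/% dim) %% 2L == 0L) 1 else -1
        emb[i, bucket] <- emb[i, bucket] + sign
      }
      nrm <- sqrt(sum(emb[i, ]^2))
      if (nrm > 0) emb[i, ] <- emb[i, ] / nrm
    }
    emb
  }
}

#' Build a semantic index (document embeddings) over a corpus
#'
#' @param corpus A trial-corpus tibble.
#' @param embedder Embedder function (see [hash_embedder()]).
#' @return A `semantic_index` object.
#' @export
semantic_index <- function(corpus, embedder = hash_embedder()) {
  corpus <- as_trial_corpus(corpus)
  emb <- if (nrow(corpus) > 0) embedder(trial_document_text(corpus)) else
    matrix(0, 0, 0)
  if (nrow(corpus) > 0 && (!is.matrix(emb) || nrow(emb) != nrow(corpus))) {
    abort("Embedder must return one row per input text.",
          class = "trialmatchr_config_error")
  }
  structure(list(trial_id = corpus$trial_id, embeddings = emb,
                 embedder = embedder),
            class = "semantic_index")
}

#' Rank trials for one keyword by embedding inner product
#'
#' All trials are ranked by descending inner product between the query
#' embedding and the precomputed document embeddings, with ties broken by
#' `trial_id`.
#'
#' @param query Keyword string.
#' @param index A [semantic_index()].
#' @return Tibble with `trial_id`, `rank`, `score`.
#' @export
semantic_rank <- function(query, index) {
  stopifnot(inherits(index, "semantic_index"))
  if (length(index$trial_id) == 0L) {
    return(tibble(trial_id = character(), rank = integer(), score = numeric()))
  }
  q <- index$embedder(query)
  if (!is.matrix(q) || ncol(q) != ncol(index$embeddings)) {
    abort(sprintf("Embedder dimension mismatch: query has %d columns, index has %d.",
                  if (is.matrix(q)) ncol(q) else -1L, ncol(index$embeddings)),
          class = "trialmatchr_config_error")
  }
  scores <- as.numeric(index$embeddings %*% q[1, ])
  ord <- order(-scores, index$trial_id)
  tibble(trial_id = index$trial_id[ord], rank = seq_along(ord),
         score = scores[ord])
}

render_keyword_prompt <- function(text, max_keywords) {
  paste0(
    "You are helping to search for clinical trials for a patient.\n",
    "Generate a list of up to ", max_keywords, " search keywords that ",
    "summarise the main medical problems of the patient, ranked from most ",
    "to least important. Respond with a JSON array of strings only.\n\n",
    "Patient note:\n", text, "\n"
  )
}

#' Generate ranked search keywords for a patient note
#'
#' The backend is asked for up to `max_keywords` keywords ordered from most to
#' least important; the response is parsed (JSON array, or one keyword per
#' line as a fallback), deduplicated case-insensitively preserving the first
#' occurrence, and truncated to `max_keywords`. The resulting 1-based position
#' is the importance rank `i` used in the fusion decay `1/i`.
#'
#' @param note One row of a patient tibble (or a list with `patient_id`,
#'   `text`).
#' @param backend An [llm_backend()].
#' @param max_keywords Maximum number of keywords (default 32).
#' @return Character vector of keywords, most important first.
#' @export
generate_keywords <- function(note, backend, max_keywords = 32L) {
  assert_scalar_number(max_keywords, "max_keywords", min = 1)
  text <- if (is.data.frame(note)) note$text[[1]] else note$text
  patient_id <- if (is.data.frame(note)) note$patient_id[[1]] else note$patient_id
  raw <- backend_call(backend, list(
    type = "keywords",
    prompt = render_keyword_prompt(text, max_keywords),
    patient_id = patient_id, max_keywords = max_keywords
  ))
  parsed <- tryCatch(jsonlite::fromJSON(strip_code_fence(raw),
                                        simplifyVector = TRUE),
                     error = function(e) NULL)
  kw <- if (!is.null(parsed) && (is.character(parsed) || is.list(parsed))) {
    as.character(unlist(parsed))
  } else {
    unlist(strsplit(raw, "\n|,")) # one-keyword-per-line fallback
  }
  kw <- compact_chr(kw)
  kw <- kw[!duplicated(tolower(kw))]
  if (length(kw) == 0L) {
    abort("Backend returned no usable keywords.",
          class = "trialmatchr_retrieval_error", raw_output = raw)
  }
  head(kw, max_keywords)
}

#' Fuse per-keyword rankings with weighted reciprocal ranks
#'
#' For trial `t_j` the fused score is
#' `s_j = sum over retrievers, sum over keywords i of
#' 1 / (i * (Rank(Ret, w_i, t_j) + C))`,
#' where `i` is the 1-based keyword importance rank and `C` is the reciprocal
#' rank fusion constant (default 20). A trial absent from one keyword's
#' ranking contributes 0 for that term (equivalent to an infinite rank).
#'
#' @param rankings Tibble with columns `retriever_id`, `keyword_index`
#'   (1-based), `trial_id`, `rank` (1-based).
#' @param C Fusion constant, must be positive.
#' @return Tibble with `trial_id` and fused `score`, sorted by descending
#'   score with ties broken by `trial_id`.
#' @export
fuse_rankings <- function(rankings, C = 20) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    abort("`C` must be a single positive number.",
          class = "trialmatchr_config_error")
  }
  assert_columns(rankings, c("retriever_id", "keyword_index", "trial_id",
                             "rank"), "rankings")
  if (nrow(rankings) == 0L) {
    return(tibble(trial_id = character(), score = numeric()))
  }
  rankings |>
    mutate(contrib = 1 / (.data$keyword_index * (.data$rank + C))) |>
    group_by(.data$trial_id) |>
    summarise(score = sum(.data$contrib), .groups = "drop") |>
    arrange(desc(.data$score), .data$trial_id)
}

#' Retrieve candidate trials for patients
#'
#' Full first-stage retrieval: generate keywords for each patient, rank trials
#' per keyword with the lexical and/or semantic retriever, fuse with
#' [fuse_rankings()], and keep the `top_k` trials with positive fused score.
#'
#' @param patients Patient tibble (see [as_patient_notes()]).
#' @param corpus Trial-corpus tibble.
#' @param backend An [llm_backend()] used for keyword generation.
#' @param embedder Embedder for the semantic retriever.
#' @param top_k Number of candidates to keep per patient (default 500).
#' @param retriever `"hybrid"` (both), `"lexical"`, or `"semantic"`.
#' @param rrf_c Reciprocal-rank-fusion constant (default 20).
#' @param max_keywords Maximum keywords per patient (default 32).
#' @param depth Per-keyword ranking truncation depth before fusion
#'   (default 1000); tail contributions beyond it are negligible.
#' @param tag Run tag for the output.
#' @return A run tibble with `patient_id`, `trial_id`, `rank`, `score`, `tag`.
#' @export
retrieve_candidates <- function(patients, corpus, backend,
                                embedder = hash_embedder(), top_k = 500L,
                                retriever = c("hybrid", "lexical", "semantic"),
                                rrf_c = 20, max_keywords = 32L,
                                depth = 1000L, tag = "trialmatchr") {
  retriever <- match.arg(retriever)
  assert_scalar_number(top_k, "top_k", min = 1)
  assert_scalar_number(depth, "depth", min = 1)
  patients <- as_patient_notes(patients)
  corpus <- as_trial_corpus(corpus)
  lex <- if (retriever != "semantic") bm25_index(corpus) else NULL
  sem <- if (retriever != "lexical") semantic_index(corpus, embedder) else NULL

  per_patient <- lapply(seq_len(nrow(patients)), function(p) {
    note <- patients[p, ]
    keywords <- generate_keywords(note, backend, max_keywords = max_keywords)
    rankings <- bind_rows(lapply(seq_along(keywords), function(i) {
      parts <- list()
      if (!is.null(lex)) {
        r <- head(bm25_rank(keywords[[i]], lex), depth)
        if (nrow(r) > 0) {
          parts$lexical <- mutate(r, retriever_id = "lexical",
                                  keyword_index = i)
        }
      }
      if (!is.null(sem)) {
        r <- head(semantic_rank(keywords[[i]], sem), depth)
        if (nrow(r) > 0) {
          parts$semantic <- mutate(r, retriever_id = "semantic",
                                   keyword_index = i)
        }
      }
      bind_rows(parts)
    }))
    fused <- fuse_rankings(rankings, C = rrf_c)
    fused <- head(fused, top_k)
    if (nrow(fused) == 0L) return(NULL)
    tibble(patient_id = note$patient_id[[1]], trial_id = fused$trial_id,
           rank = seq_len(nrow(fused)), score = fused$score, tag = tag)
  })
  bind_rows(per_patient)
}
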