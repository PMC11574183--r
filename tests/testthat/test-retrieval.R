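test_that("keyword generation parses, deduplicates and truncates", {
  note <- list(patient_id = "p1", text = "irrelevant")
  be <- scripted_backend(list(keywords = '["x", "X", "y"]'))
  expect_identical(generate_keywords(note, be), c("x", "y"))

  many <- scripted_backend(list(
    keywords = jsonlite::toJSON(sprintf("kw%02d", 1:40))))
  expect_length(generate_keywords(note, many), 32L)
  expect_length(generate_keywords(note, many, max_keywords = 5), 5L)

  empty <- scripted_backend(list(keywords = "[]"))
  err <- expect_error(generate_keywords(note, empty),
                      class = "trialmatchr_retrieval_error")
  expect_identical(err$raw_output, "[]")

  # plain-line fallback for backends that do not emit JSON
  lines <- scripted_backend(list(keywords = "diabetes\ninsulin\n"))
  expect_identical(generate_keywords(note, lines), c("diabetes", "insulin"))
})

test_that("oracle keyword backend echoes the generator's salience order", {
  co <- shared_cohort()
  be <- mock_backend(co, noise = 0, seed = 1)
  for (i in seq_len(nrow(co$patients))) {
    kw <- generate_keywords(co$patients[i, ], be)
    expect_identical(kw, co$patient_keywords$keywords[[i]])
    # primary condition is always the most important keyword
    expect_true(kw[[1]] %in% trialmatchr:::cohort_schema()$conditions)
  }
})

test_that("bm25 ranking matches a from-scratch textbook computation", {
  idx <- bm25_index(tiny_corpus())
  # single matching document at rank 1
  r <- bm25_rank("headache", idx)
  expect_identical(r$trial_id[[1]], "NCT00000001")
  expect_identical(nrow(r), 1L)
  # absent term: empty ranking, not an error
  expect_identical(nrow(bm25_rank("zzz absent", idx)), 0L)
  expect_identical(nrow(bm25_rank("???", idx)), 0L)

  co <- generate_cohort(n_patients = 2, n_trials = 50, seed = 11)
  idx50 <- bm25_index(co$corpus)
  docs <- trialmatchr:::trial_document_text(co$corpus)
  queries <- c("glioblastoma", "metformin", "type 2 diabetes mellitus",
               "hemoglobin", "warfarin")
  for (q in queries) {
    expected <- oracle_bm25_score(q, docs)
    got <- bm25_rank(q, idx50)
    lookup <- setNames(expected, co$corpus$trial_id)
    expect_lt(max(abs(got$score - lookup[got$trial_id])), 1e-9)
    # every positively scored document is present
    expect_setequal(got$trial_id, co$corpus$trial_id[expected > 0])
  }
})

test_that("semantic ranking follows inner products with deterministic ties", {
  corp <- tiny_corpus()
  # one-hot embedder over a ground-truth vocabulary: ranking must equal
  # attribute-overlap ordering
  vocab <- c("diabetes", "insulin", "aspirin", "headache", "diet")
  onehot <- function(x) {
    toks <- trialmatchr:::tokenize(x)
    t(vapply(toks, function(t) vapply(vocab, function(v) sum(t == v),
                                      numeric(1)), numeric(length(vocab))))
  }
  idx <- semantic_index(corp, onehot)
  r <- semantic_rank("diabetes insulin", idx)
  overlap <- as.numeric(onehot(trialmatchr:::trial_document_text(corp)) %*%
                          onehot("diabetes insulin")[1, ])
  expect_identical(r$trial_id,
                   corp$trial_id[order(-overlap, corp$trial_id)])

  # identical documents: all tied, ordered by trial_id
  same <- corp
  same$title <- rep("same", 3); same$brief_summary <- rep("same", 3)
  same$conditions <- same$interventions <- list("x", "x", "x")
  same$inclusion_criteria <- same$exclusion_criteria <-
    list("c.", "c.", "c.")
  r2 <- semantic_rank("x", semantic_index(same, hash_embedder(64)))
  expect_identical(r2$trial_id, sort(same$trial_id))

  # empty corpus: empty ranking
  r3 <- semantic_rank("x", semantic_index(corp[0, ], hash_embedder(64)))
  expect_identical(nrow(r3), 0L)

  # dimension mismatch is a configuration error
  bad <- semantic_index(corp, hash_embedder(64))
  bad$embedder <- hash_embedder(32)
  expect_error(semantic_rank("x", bad), class = "trialmatchr_config_error")
})

test_that("reciprocal rank fusion matches direct substitution", {
  one <- tibble::tibble(retriever_id = "lexical", keyword_index = 1L,
                        trial_id = "t1", rank = 1L)
  expect_equal(fuse_rankings(one, C = 20)$score, 1 / 21)
  both <- dplyr::bind_rows(one, dplyr::mutate(one, retriever_id = "semantic"))
  expect_equal(fuse_rankings(both, C = 20)$score, 2 / 21)
  deep <- tibble::tibble(retriever_id = "lexical", keyword_index = 2L,
                         trial_id = "t9", rank = 3L)
  expect_equal(fuse_rankings(deep, C = 20)$score, 1 / 46)
  expect_error(fuse_rankings(one, C = 0), class = "trialmatchr_config_error")
  expect_error(fuse_rankings(one, C = -3), class = "trialmatchr_config_error")
})

test_that("fusion equals the brute-force double sum on random instances", {
  # 100 random instances: 100 trials, 10 keywords, 2 retrievers
  withr::local_seed(42)
  trials <- sprintf("t%03d", 1:100)
  for (rep in 1:100) {
    rankings <- dplyr::bind_rows(lapply(c("lexical", "semantic"), function(ret) {
      dplyr::bind_rows(lapply(1:10, function(i) {
        n <- sample(0:100, 1)
        if (n == 0) return(NULL)
        tibble::tibble(retriever_id = ret, keyword_index = i,
                       trial_id = sample(trials, n), rank = seq_len(n))
      }))
    }))
    fused <- fuse_rankings(rankings, C = 20)
    lookup <- function(ret, i, t) {
      hit <- rankings$rank[rankings$retriever_id == ret &
                             rankings$keyword_index == i &
                             rankings$trial_id == t]
      if (length(hit) == 0) NA_integer_ else hit
    }
    check <- sample(fused$trial_id, min(5, nrow(fused)))
    for (t in check) {
      expected <- oracle_fused_score(t, lookup, c("lexical", "semantic"),
                                     10, 20)
      expect_lt(abs(fused$score[fused$trial_id == t] - expected), 1e-12)
    }
    # every fused trial appears in at least one ranking and scores > 0
    expect_true(all(fused$score > 0))
    expect_setequal(fused$trial_id, unique(rankings$trial_id))
  }
})

test_that("fused score is monotone in any single rank", {
  base <- tibble::tibble(
    retriever_id = c("lexical", "semantic", "lexical"),
    keyword_index = c(1L, 1L, 2L), trial_id = "t1", rank = c(5L, 8L, 2L))
  s0 <- fuse_rankings(base)$score
  for (row in 1:3) {
    worse <- base; worse$rank[row] <- worse$rank[row] + 1L
    expect_lt(fuse_rankings(worse)$score, s0)
  }
})

test_that("candidate retrieval respects top_k, ties, and recall monotonicity", {
  co <- shared_cohort()
  be <- mock_backend(co, noise = 0, seed = 1)
  run <- retrieve_candidates(co$patients, co$corpus, be, top_k = 1000)
  # top_k larger than the corpus: all positively scored trials returned
  expect_true(all(table(run$patient_id) <= nrow(co$corpus)))
  run10 <- retrieve_candidates(co$patients[1, ], co$corpus, be, top_k = 10)
  expect_identical(nrow(run10), 10L)

  # recall is non-decreasing in k
  rc <- recall_curve(run, co$qrels, ks = c(5, 10, 20, 40, 60))
  expect_true(all(diff(rc$recall) >= 0))
  # full-depth recall of the whole judged collection is 1
  expect_equal(rc$recall[rc$k == 60], 1)

  # every ground-truth-relevant trial appears in the top 50
  relevant <- co$qrels[co$qrels$grade > 0, ]
  top50 <- run[run$rank <= 50, ]
  found <- dplyr::semi_join(relevant, top50, by = c("patient_id", "trial_id"))
  expect_identical(nrow(found), nrow(relevant))

  # equal fused scores order by trial_id
  f <- fuse_rankings(tibble::tibble(
    retriever_id = "lexical", keyword_index = c(1L, 1L),
    trial_id = c("tB", "tA"), rank = c(3L, 3L)))
  expect_identical(f$trial_id, c("tA", "tB"))
})

test_that("retriever modes run lexical-only and semantic-only ablations", {
  co <- shared_cohort()
  be <- mock_backend(co, noise = 0, seed = 1)
  p1 <- co$patients[1, ]
  for (mode in c("lexical", "semantic", "hybrid")) {
    run <- retrieve_candidates(p1, co$corpus, be, top_k = 20,
                               retriever = mode)
    expect_identical(nrow(run), 20L)
    expect_identical(run$rank, 1:20)
  }
})
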