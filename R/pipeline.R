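# End-to-end wiring of the three stages plus evaluation, with a provenance
# fingerprint, on-disk backend-response caching, and deterministic writers so
# that re-running an unchanged configuration changes no output bytes.

#' Pipeline configuration
#'
#' Collects the tunable constants of the pipeline with their default values:
#' reciprocal-rank-fusion constant `C = 20`, up to 32 keywords per patient,
#' 500 retrieval candidates per patient, LLM-score normalization 100, and
#' backend temperature 0 for deterministic outputs. The configuration is
#' serialized alongside every pipeline run for provenance.
#'
#' @param top_k Candidates kept per patient.
#' @param rrf_c Fusion constant.
#' @param max_keywords Keyword cap per patient.
#' @param retriever `"hybrid"`, `"lexical"`, or `"semantic"`.
#' @param feature,task Trial-level scoring feature and task for the final
#'   ranking (see [task_score()]).
#' @param excluding_feature Feature used for the excluding run. Defaults to
#'   the LLM eligibility score: in the combined score the relevance and
#'   eligibility terms cancel for explicitly excluded pairs, which makes them
#'   indistinguishable from irrelevant ones, whereas the eligibility score
#'   separates the excluded class directly.
#' @param normalization LLM-score divisor in the feature combination.
#' @param seed Integer seed recorded for provenance.
#' @param cache_dir Backend-response cache directory, or `NULL` to place it
#'   under the output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(top_k = 500L, rrf_c = 20, max_keywords = 32L,
                       retriever = "hybrid", feature = "combined",
                       excluding_feature = "eligibility",
                       task = "ranking", normalization = 100, seed = 1L,
                       cache_dir = NULL) {
  assert_scalar_number(top_k, "top_k", min = 1)
  assert_scalar_number(rrf_c, "rrf_c", min = 1e-12)
  assert_scalar_number(max_keywords, "max_keywords", min = 1)
  retriever <- match.arg(retriever, c("hybrid", "lexical", "semantic"))
  task <- match.arg(task, c("ranking", "excluding"))
  structure(list(top_k = as.integer(top_k), rrf_c = rrf_c,
                 max_keywords = as.integer(max_keywords),
                 retriever = retriever, feature = feature,
                 excluding_feature = excluding_feature, task = task,
                 normalization = normalization, seed = as.integer(seed),
                 temperature = 0, cache_dir = cache_dir),
            class = "run_config")
}

#' Run the full matching pipeline
#'
#' Retrieval, matching, trial-level scoring/ranking, and (when qrels are
#' supplied) evaluation, writing each stage's artifact into `out_dir`:
#' `config.json` (provenance fingerprint), `retrieval_run.txt`,
#' `matches.jsonl`, `failed_pairs.jsonl` (pairs whose backend output failed
#' to parse or validate, listed for resumption), `scores.jsonl`,
#' `ranking_run.txt`, `excluding_run.txt`, and `report.json` / `report.tsv`.
#' Backend responses are cached by content hash in the cache directory, so a
#' re-run over completed pairs makes zero duplicate backend calls and
#' produces byte-identical outputs.
#'
#' @param patients Patient tibble, or path to a patients JSONL file.
#' @param corpus Trial-corpus tibble, or path to a corpus JSONL file.
#' @param backend An [llm_backend()].
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param qrels Optional qrels tibble or file path; enables the evaluation
#'   stage.
#' @param embedder Embedder for the semantic retriever.
#' @return Invisibly, a list with the stage outputs (`candidates`, `matches`,
#'   `scores`, `ranking`, `excluding`, `evaluation`) and `paths`.
#' @export
run_pipeline <- function(patients, corpus, backend, out_dir,
                         config = run_config(), qrels = NULL,
                         embedder = hash_embedder()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(patients)) patients <- read_patient_notes(patients)
  if (is.character(corpus)) corpus <- read_trial_corpus(corpus)
  if (is.character(qrels)) qrels <- read_qrels(qrels)
  patients <- as_patient_notes(patients)
  corpus <- as_trial_corpus(corpus)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- config$cache_dir %||% file.path(out_dir, "backend_cache")
  backend <- cached_backend(backend, cache_dir)

  fingerprint <- c(unclass(config)[setdiff(names(config), "cache_dir")],
                   list(backend_model = backend$model_id,
                        n_patients = nrow(patients),
                        n_trials = nrow(corpus)))
  jsonlite::write_json(fingerprint, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  candidates <- retrieve_candidates(
    patients, corpus, backend, embedder = embedder, top_k = config$top_k,
    retriever = config$retriever, rrf_c = config$rrf_c,
    max_keywords = config$max_keywords)
  write_trec_run(candidates, file.path(out_dir, "retrieval_run.txt"))

  batch <- match_candidates(candidates, patients, corpus, backend)
  write_matches(batch$results, file.path(out_dir, "matches.jsonl"))
  write_jsonl(lapply(seq_len(nrow(batch$failures)), function(i)
    as.list(batch$failures[i, ])),
    file.path(out_dir, "failed_pairs.jsonl"))

  scores <- score_trials(batch$results, backend,
                         normalization = config$normalization)
  write_scores(scores, file.path(out_dir, "scores.jsonl"))
  ranking <- rank_trials(scores, feature = config$feature, task = "ranking",
                         normalization = config$normalization)
  write_trec_run(ranking, file.path(out_dir, "ranking_run.txt"))
  excluding <- rank_trials(scores, feature = config$excluding_feature,
                           task = "excluding",
                           normalization = config$normalization)
  write_trec_run(excluding, file.path(out_dir, "excluding_run.txt"))

  evaluation <- NULL
  if (!is.null(qrels)) {
    evaluation <- list(
      retrieval = evaluate_run(candidates, qrels,
                               metrics = sprintf("recall@%d", config$top_k)),
      ranking = evaluate_run(ranking, qrels, metrics = c("ndcg@10", "p@10")),
      excluding = evaluate_run(excluding, qrels, metrics = "auroc"))
    report <- bind_rows(
      mutate(evaluation$retrieval$summary, stage = "retrieval"),
      mutate(evaluation$ranking$summary, stage = "ranking"),
      mutate(evaluation$excluding$summary, stage = "excluding"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  invisible(list(candidates = candidates, matches = batch, scores = scores,
                 ranking = ranking, excluding = excluding,
                 evaluation = evaluation,
                 paths = file.path(out_dir, c(
                   "config.json", "retrieval_run.txt", "matches.jsonl",
                   "failed_pairs.jsonl", "scores.jsonl", "ranking_run.txt",
                   "excluding_run.txt"))))
}
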