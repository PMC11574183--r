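# Criterion-level eligibility matching: per (patient, trial) pair, one
# backend call covers all inclusion criteria and a second covers all
# exclusion criteria. Each criterion's structured output carries a free-text
# relevance explanation, the 0-based IDs of the note sentences that support
# it, and an eligibility label from the type-specific four-value set. The
# prompt asks for the explanation before the label so the prediction is
# grounded in stated reasoning.

#' Build the matching prompt for one criterion type
#'
#' The prompt contains the task description, the trial background (title,
#' conditions, interventions, brief summary), the numbered criterion list for
#' the requested type (0-based, corpus order), the label set for that type,
#' and the patient note rendered with 0-based sentence IDs. The model is
#' instructed to produce, per criterion, the explanation first, then the
#' relevant sentence IDs, then the eligibility label, as a JSON object keyed
#' by criterion index.
#'
#' @param note One row of a patient tibble.
#' @param trial One row of a trial-corpus tibble.
#' @param criterion_type `"inclusion"` or `"exclusion"`.
#' @return A list with `criterion_type`, `n_criteria`, `n_sentences`,
#'   `rendered_text`.
#' @export
build_matching_prompt <- function(note, trial,
                                  criterion_type = c("inclusion", "exclusion")) {
  criterion_type <- match.arg(criterion_type)
  criteria <- trial[[paste0(criterion_type, "_criteria")]][[1]]
  if (length(criteria) == 0L) {
    abort(sprintf("Trial %s has no %s criteria; skip this call.",
                  trial$trial_id[[1]], criterion_type),
          class = "trialmatchr_empty_criteria")
  }
  sentences <- note$sentences[[1]]
  labels <- gsub("_", " ", eligibility_labels(criterion_type))
  rendered <- paste0(
    "You assess the eligibility of a patient against the ", criterion_type,
    " criteria of a clinical trial, one criterion at a time.\n\n",
    "Trial background:\nTitle: ", trial$title[[1]], "\n",
    "Conditions: ", paste(trial$conditions[[1]], collapse = "; "), "\n",
    "Interventions: ", paste(trial$interventions[[1]], collapse = "; "), "\n",
    "Summary: ", trial$brief_summary[[1]], "\n\n",
    toupper(substring(criterion_type, 1, 1)),
    substring(criterion_type, 2), " criteria (numbered from 0):\n",
    paste(sprintf("%d. %s", seq_along(criteria) - 1L, criteria),
          collapse = "\n"), "\n\n",
    "Patient note, one sentence per line, numbered from 0:\n",
    number_sentences(sentences), "\n\n",
    "For each criterion, first write a short explanation of how the patient ",
    "relates to the criterion, then list the IDs of the note sentences that ",
    "are relevant to it, then give the eligibility label. The label must be ",
    "one of: ", paste(labels, collapse = ", "), ".\n",
    "Answer with a JSON object keyed by the criterion index, each value an ",
    "object with fields \"explanation\" (string), \"sentence_ids\" (array of ",
    "integers), and \"label\" (string). Output JSON only.\n"
  )
  list(criterion_type = criterion_type, n_criteria = length(criteria),
       n_sentences = length(sentences), rendered_text = rendered)
}

sentinel_result <- function(criterion_type) {
  list(explanation = "", sentence_ids = integer(),
       label = "not_enough_information", imputed = TRUE)
}

#' Parse and validate a structured matching response
#'
#' Strict validation of the backend's JSON output for one criterion type:
#' labels must belong to the label set for that type (a wrong-type label,
#' e.g. `included` on an exclusion criterion, is a validation error naming
#' the criterion index); sentence IDs are deduplicated and out-of-range IDs
#' are dropped with a warning; criteria missing from the response are filled
#' with a flagged sentinel (`not_enough_information`, no evidence). A
#' response that cannot be parsed at all raises a parse error that retains
#' the raw text.
#'
#' @param raw Raw backend response text.
#' @param criterion_type `"inclusion"` or `"exclusion"`.
#' @param n_criteria Expected number of criteria of this type.
#' @param n_sentences Number of sentences in the patient note.
#' @return Tibble with `criterion_index` (0-based), `criterion_type`,
#'   `explanation`, `sentence_ids` (list), `label`, `imputed`.
#' @export
parse_matching_output <- function(raw, criterion_type, n_criteria, n_sentences) {
  criterion_type <- match.arg(criterion_type, c("inclusion", "exclusion"))
  parsed <- tryCatch(
    jsonlite::fromJSON(strip_code_fence(raw), simplifyVector = FALSE),
    error = function(e) e
  )
  if (inherits(parsed, "error") || !is.list(parsed)) {
    abort(sprintf("Could not parse %s matching output as JSON: %s",
                  criterion_type,
                  if (inherits(parsed, "error")) conditionMessage(parsed)
                  else "response is not an object"),
          class = "trialmatchr_parse_error", raw_output = raw)
  }
  n <- n_criteria
  explanation <- character(n); label <- character(n)
  sentence_ids <- vector("list", n); imputed <- logical(n)
  for (i in seq_len(n)) {
    idx <- i - 1L
    item <- parsed[[as.character(idx)]]
    if (is.null(item) || !is.list(item) || is.null(item$label)) {
      item <- sentinel_result(criterion_type)
    } else {
      item$imputed <- FALSE
    }
    label[[i]] <- validate_label(item$label, criterion_type,
                                 criterion_index = idx)
    ids <- unique(as.integer(unlist(item$sentence_ids)))
    ids <- ids[!is.na(ids)]
    in_range <- ids >= 0L & ids <= n_sentences - 1L
    if (any(!in_range)) {
      warn(sprintf(
        "Dropping out-of-range sentence id(s) %s for %s criterion %d (note has %d sentences).",
        paste(ids[!in_range], collapse = ", "), criterion_type, idx, n_sentences),
        class = "trialmatchr_sentence_id_warning")
      ids <- ids[in_range]
    }
    explanation[[i]] <- as.character(item$explanation %||% "")
    sentence_ids[[i]] <- sort(ids)
    imputed[[i]] <- isTRUE(item$imputed)
  }
  tibble::new_tibble(list(
    criterion_index = seq_len(n) - 1L,
    criterion_type = rep(criterion_type, n),
    explanation = explanation, sentence_ids = sentence_ids,
    label = label, imputed = imputed), nrow = n)
}

#' Match one patient against one trial
#'
#' Makes at most two backend calls — one covering all inclusion criteria, one
#' covering all exclusion criteria; a call is skipped when the trial has no
#' criteria of that type — parses both responses, and returns the assembled
#' criterion-level results together with the verbatim raw outputs for audit.
#'
#' @param note One row of a patient tibble.
#' @param trial One row of a trial-corpus tibble.
#' @param backend An [llm_backend()].
#' @return A list of class `trial_match` with elements `patient_id`,
#'   `trial_id`, `results` (criterion-level tibble) and `raw_outputs` (named
#'   list of the verbatim responses).
#' @export
match_trial <- function(note, trial, backend) {
  results <- list(); raw_outputs <- list()
  for (type in c("inclusion", "exclusion")) {
    n_crit <- length(trial[[paste0(type, "_criteria")]][[1]])
    if (n_crit == 0L) next
    prompt <- build_matching_prompt(note, trial, type)
    raw <- backend_call(backend, list(
      type = "matching", prompt = prompt$rendered_text,
      criterion_type = type, patient_id = note$patient_id[[1]],
      trial_id = trial$trial_id[[1]], n_criteria = n_crit,
      n_sentences = prompt$n_sentences
    ))
    raw_outputs[[type]] <- raw
    results[[type]] <- parse_matching_output(raw, type, n_crit,
                                             prompt$n_sentences)
  }
  res <- if (length(results) > 0) bind_rows(results) else
    tibble::new_tibble(list(criterion_index = integer(),
                            criterion_type = character(),
                            explanation = character(), sentence_ids = list(),
                            label = character(), imputed = logical()),
                       nrow = 0L)
  res <- tibble::new_tibble(
    c(list(patient_id = rep(note$patient_id[[1]], nrow(res)),
           trial_id = rep(trial$trial_id[[1]], nrow(res))),
      as.list(res)), nrow = nrow(res))
  structure(list(patient_id = note$patient_id[[1]],
                 trial_id = trial$trial_id[[1]],
                 results = res, raw_outputs = raw_outputs),
            class = "trial_match")
}

#' Match all candidate pairs from a retrieval run
#'
#' Iterates over the (patient, trial) pairs of a candidate run, matching each
#' with [match_trial()]. A pair whose backend response fails to parse or
#' validate is recorded as failed — with its error message — and the batch
#' continues; no labels are imputed for failed pairs.
#'
#' @param candidates Run tibble (`patient_id`, `trial_id`, ...), e.g. from
#'   [retrieve_candidates()].
#' @param patients Patient tibble.
#' @param corpus Trial-corpus tibble.
#' @param backend An [llm_backend()].
#' @return A list of class `trial_match_batch` with `results` (criterion-level
#'   tibble across all successful pairs) and `failures` (tibble of
#'   `patient_id`, `trial_id`, `error`).
#' @export
match_candidates <- function(candidates, patients, corpus, backend) {
  assert_columns(candidates, c("patient_id", "trial_id"), "candidates")
  patients <- as_patient_notes(patients)
  corpus <- as_trial_corpus(corpus)
  unknown_p <- setdiff(unique(candidates$patient_id), patients$patient_id)
  unknown_t <- setdiff(unique(candidates$trial_id), corpus$trial_id)
  if (length(unknown_p) > 0L || length(unknown_t) > 0L) {
    abort(sprintf("Candidates reference unknown ids: %s.",
                  paste(c(unknown_p, unknown_t), collapse = ", ")),
          class = "trialmatchr_validation_error")
  }
  p_idx <- match(candidates$patient_id, patients$patient_id)
  t_idx <- match(candidates$trial_id, corpus$trial_id)
  p_rows <- lapply(seq_len(nrow(patients)), function(i) patients[i, ])
  t_rows <- lapply(seq_len(nrow(corpus)), function(i) corpus[i, ])
  out <- vector("list", nrow(candidates))
  failures <- list()
  for (i in seq_len(nrow(candidates))) {
    m <- tryCatch(
      match_trial(p_rows[[p_idx[i]]], t_rows[[t_idx[i]]], backend),
      trialmatchr_parse_error = function(e) e,
      trialmatchr_validation_error = function(e) e
    )
    if (inherits(m, "error")) {
      failures[[length(failures) + 1L]] <- tibble(
        patient_id = candidates$patient_id[[i]],
        trial_id = candidates$trial_id[[i]],
        error = conditionMessage(m))
    } else {
      out[[i]] <- m$results
    }
  }
  empty_results <- tibble::new_tibble(
    list(patient_id = character(), trial_id = character(),
         criterion_index = integer(), criterion_type = character(),
         explanation = character(), sentence_ids = list(),
         label = character(), imputed = logical()), nrow = 0L)
  results <- bind_rows(c(list(empty_results), out))
  structure(list(
    results = results,
    failures = if (length(failures) > 0) bind_rows(failures) else
      tibble(patient_id = character(), trial_id = character(),
             error = character())
  ), class = "trial_match_batch")
}

#' @export
print.trial_match_batch <- function(x, ...) {
  cat(sprintf("<trial_match_batch: %d criterion results over %d pairs, %d failed pairs>\n",
              nrow(x$results),
              nrow(unique(x$results[, c("patient_id", "trial_id")])),
              nrow(x$failures)))
  invisible(x)
}
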