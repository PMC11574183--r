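# Readers and writers for the interchange formats: JSONL corpora and notes,
# TREC qrels and run files, and the criterion-level matching / trial-level
# score JSONL outputs. All writers are deterministic (no timestamps) so that
# re-runs with unchanged inputs are byte-identical.

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE,
         simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a trial corpus from JSONL
#'
#' One JSON object per line with fields `trial_id`, `title`, `conditions`,
#' `interventions`, `brief_summary`, `inclusion_criteria`,
#' `exclusion_criteria` (criteria as arrays of strings, one criterion each).
#'
#' @param path Path to a JSONL file.
#' @return A validated trial-corpus tibble (see [as_trial_corpus()]).
#' @export
read_trial_corpus <- function(path) {
  recs <- read_jsonl(path)
  corpus <- tibble(
    trial_id = map_chr(recs, ~ as.character(.x$trial_id %||% "")),
    title = map_chr(recs, ~ as.character(.x$title %||% "")),
    conditions = map(recs, ~ as.character(.x$conditions %||% character())),
    interventions = map(recs, ~ as.character(.x$interventions %||% character())),
    brief_summary = map_chr(recs, ~ as.character(.x$brief_summary %||% "")),
    inclusion_criteria = map(recs, ~ as.character(.x$inclusion_criteria %||% character())),
    exclusion_criteria = map(recs, ~ as.character(.x$exclusion_criteria %||% character()))
  )
  as_trial_corpus(corpus)
}

#' Write a trial corpus to JSONL
#' @param corpus A trial-corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_corpus <- function(corpus, path) {
  corpus <- as_trial_corpus(corpus)
  recs <- lapply(seq_len(nrow(corpus)), function(i) {
    list(trial_id = corpus$trial_id[[i]],
         title = corpus$title[[i]],
         conditions = as.list(corpus$conditions[[i]]),
         interventions = as.list(corpus$interventions[[i]]),
         brief_summary = corpus$brief_summary[[i]],
         inclusion_criteria = as.list(corpus$inclusion_criteria[[i]]),
         exclusion_criteria = as.list(corpus$exclusion_criteria[[i]]))
  })
  write_jsonl(recs, path)
}

#' Read patient notes from JSONL
#'
#' One JSON object per line with fields `patient_id` and `text`.
#'
#' @param path Path to a JSONL file.
#' @return A patient tibble with indexed sentences (see [as_patient_notes()]).
#' @export
read_patient_notes <- function(path) {
  recs <- read_jsonl(path)
  as_patient_notes(tibble(
    patient_id = map_chr(recs, ~ as.character(.x$patient_id %||% "")),
    text = map_chr(recs, ~ as.character(.x$text %||% ""))
  ))
}

#' Write patient notes to JSONL
#' @param patients Patient tibble with `patient_id` and `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_notes <- function(patients, path) {
  recs <- lapply(seq_len(nrow(patients)), function(i) {
    list(patient_id = patients$patient_id[[i]], text = patients$text[[i]])
  })
  write_jsonl(recs, path)
}

#' Read TREC-format relevance judgments (qrels)
#'
#' Whitespace-separated lines `patient_id 0 trial_id grade` with graded
#' relevance 0 (irrelevant / unjudged), 1 (excluded or potential), or
#' 2 (eligible).
#'
#' @param path Path to a qrels file.
#' @return Tibble with columns `patient_id`, `trial_id`, `grade`.
#' @export
read_qrels <- function(path) {
  df <- read.table(path, header = FALSE, col.names = c("patient_id", "iter",
                                                       "trial_id", "grade"),
                   colClasses = c("character", "character", "character",
                                  "integer"))
  as_tibble(df)[, c("patient_id", "trial_id", "grade")]
}

#' Write TREC-format relevance judgments
#' @param qrels Tibble with `patient_id`, `trial_id`, `grade`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(qrels, path) {
  assert_columns(qrels, c("patient_id", "trial_id", "grade"), "qrels")
  writeLines(sprintf("%s 0 %s %d", qrels$patient_id, qrels$trial_id,
                     as.integer(qrels$grade)), path, useBytes = TRUE)
  invisible(path)
}

#' Read a TREC-format run file
#'
#' Lines `patient_id Q0 trial_id rank score tag`.
#'
#' @param path Path to a run file.
#' @return Tibble with `patient_id`, `trial_id`, `rank`, `score`, `tag`.
#' @export
read_trec_run <- function(path) {
  df <- read.table(path, header = FALSE,
                   col.names = c("patient_id", "q0", "trial_id", "rank",
                                 "score", "tag"),
                   colClasses = c("character", "character", "character",
                                  "integer", "numeric", "character"))
  as_tibble(df)[, c("patient_id", "trial_id", "rank", "score", "tag")]
}

#' Write a TREC-format run file
#' @param run Tibble with `patient_id`, `trial_id`, `rank`, `score` (and
#'   optionally `tag`).
#' @param path Output path.
#' @param tag Run tag used when the tibble has no `tag` column.
#' @return `path`, invisibly.
#' @export
write_trec_run <- function(run, path, tag = "trialmatchr") {
  assert_columns(run, c("patient_id", "trial_id", "rank", "score"), "run")
  tags <- if ("tag" %in% names(run)) run$tag else rep(tag, nrow(run))
  writeLines(sprintf("%s Q0 %s %d %.10g %s", run$patient_id, run$trial_id,
                     as.integer(run$rank), run$score, tags),
             path, useBytes = TRUE)
  invisible(path)
}

#' Write criterion-level matching results to JSONL
#'
#' One object per (patient, trial) pair with the per-criterion explanations,
#' evidence sentence IDs and eligibility labels. `schema_version` is recorded
#' in every line.
#'
#' @param matches Criterion-level results tibble (see [match_candidates()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  assert_columns(matches, c("patient_id", "trial_id", "criterion_type",
                            "criterion_index", "explanation", "sentence_ids",
                            "label"), "matches")
  key <- paste(matches$patient_id, matches$trial_id, sep = "\r")
  recs <- lapply(split(seq_len(nrow(matches)), factor(key, levels = unique(key))),
                 function(idx) {
    sub <- matches[idx, ]
    crit <- function(type) {
      s <- sub[sub$criterion_type == type, ]
      s <- s[order(s$criterion_index), ]
      lapply(seq_len(nrow(s)), function(i) {
        list(criterion_index = s$criterion_index[[i]],
             explanation = s$explanation[[i]],
             sentence_ids = as.list(s$sentence_ids[[i]]),
             label = s$label[[i]])
      })
    }
    list(schema_version = 1L,
         patient_id = sub$patient_id[[1]],
         trial_id = sub$trial_id[[1]],
         inclusion = crit("inclusion"),
         exclusion = crit("exclusion"))
  })
  write_jsonl(unname(recs), path)
}

#' Read criterion-level matching results from JSONL
#' @param path Path written by [write_matches()].
#' @return Criterion-level results tibble.
#' @export
read_matches <- function(path) {
  recs <- read_jsonl(path)
  rows <- lapply(recs, function(r) {
    one <- function(type, items) {
      if (length(items) == 0L) return(NULL)
      tibble(patient_id = r$patient_id, trial_id = r$trial_id,
             criterion_type = type,
             criterion_index = map_int(items, ~ as.integer(.x$criterion_index)),
             explanation = map_chr(items, ~ as.character(.x$explanation)),
             sentence_ids = map(items, ~ as.integer(unlist(.x$sentence_ids))),
             label = map_chr(items, ~ as.character(.x$label)))
    }
    bind_rows(one("inclusion", r$inclusion), one("exclusion", r$exclusion))
  })
  bind_rows(rows)
}

#' Write trial-level score sets to JSONL
#' @param scores Trial-score tibble (see [score_trials()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  recs <- lapply(seq_len(nrow(scores)), function(i) as.list(scores[i, ]))
  write_jsonl(recs, path)
}

#' Read trial-level score sets from JSONL
#' @param path Path written by [write_scores()].
#' @return Trial-score tibble.
#' @export
read_scores <- function(path) {
  bind_rows(lapply(read_jsonl(path), as_tibble))
}
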