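#' Validate a clinical-trial corpus
#'
#' A corpus is a tibble with one row per trial and columns `trial_id`,
#' `title`, `conditions` (list of character), `interventions` (list of
#' character), `brief_summary`, `inclusion_criteria` and `exclusion_criteria`
#' (each a list column of character vectors, one criterion per element, in
#' protocol order). Criterion indices used throughout the package are 0-based
#' positions within these lists.
#'
#' @param corpus A data frame of trials.
#' @return The validated corpus as a tibble (criterion texts stripped of
#'   surrounding whitespace).
#' @export
as_trial_corpus <- function(corpus) {
  corpus <- as_tibble(corpus)
  assert_columns(corpus, c("trial_id", "title", "conditions", "interventions",
                           "brief_summary", "inclusion_criteria",
                           "exclusion_criteria"), "Trial corpus")
  if (anyNA(corpus$trial_id) || any(!nzchar(trimws(corpus$trial_id)))) {
    abort("All `trial_id` values must be non-empty.",
          class = "trialmatchr_validation_error")
  }
  if (anyDuplicated(corpus$trial_id)) {
    abort(sprintf("Duplicated trial_id(s): %s.",
                  paste(unique(corpus$trial_id[duplicated(corpus$trial_id)]),
                        collapse = ", ")),
          class = "trialmatchr_validation_error")
  }
  clean <- function(x) lapply(x, function(v) compact_chr(as.character(v %||% character())))
  corpus$conditions <- clean(corpus$conditions)
  corpus$interventions <- clean(corpus$interventions)
  corpus$inclusion_criteria <- clean(corpus$inclusion_criteria)
  corpus$exclusion_criteria <- clean(corpus$exclusion_criteria)
  corpus
}

#' Validate patient notes and index their sentences
#'
#' Patients are a tibble with columns `patient_id` and `text`. This adds (or
#' validates) a `sentences` list column produced by [split_sentences()], the
#' 0-based sentence index being the evidence coordinate system used by the
#' matching stage.
#'
#' @param patients A data frame with `patient_id` and `text` columns.
#' @return Tibble with an added `sentences` list column.
#' @export
as_patient_notes <- function(patients) {
  patients <- as_tibble(patients)
  assert_columns(patients, c("patient_id", "text"), "Patient table")
  if (anyDuplicated(patients$patient_id)) {
    abort("Duplicated patient_id values.", class = "trialmatchr_validation_error")
  }
  if (!("sentences" %in% names(patients))) {
    patients$sentences <- lapply(patients$text, split_sentences)
  }
  patients
}

# Full searchable text of one trial row (used by both retrievers).
trial_document_text <- function(corpus) {
  vapply(seq_len(nrow(corpus)), function(i) {
    paste(c(corpus$title[[i]],
            corpus$conditions[[i]],
            corpus$interventions[[i]],
            corpus$brief_summary[[i]],
            corpus$inclusion_criteria[[i]],
            corpus$exclusion_criteria[[i]]), collapse = " ")
  }, character(1))
}
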