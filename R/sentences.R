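#' Split free text into sentences
#'
#' Deterministic rule-based sentence segmentation used to index patient notes:
#' the note is split after `.`, `!` or `?` when followed by whitespace and a
#' capital letter or digit. A small protected-abbreviation list ("Dr.", "Mr.",
#' "Mrs.", "Ms.", "vs.", "e.g.", "i.e.", "approx.", "no.", "St.") and decimal
#' numbers are never treated as sentence boundaries. Sentence IDs are the
#' 0-based positions in the returned list; all downstream evidence references
#' ("relevant sentence IDs") use these indices.
#'
#' @param text A single non-empty character string.
#' @return Character vector of sentences, in order.
#' @export
#' @examples
#' split_sentences("A 63-year-old male. He takes metformin. HbA1c is 6.8 %.")
split_sentences <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    abort("`text` must be a single non-empty string.",
          class = "trialmatchr_validation_error")
  }
  abbrev <- c("Dr", "Mr", "Mrs", "Ms", "vs", "e\\.g", "i\\.e", "approx",
              "No", "no", "St")
  masked <- text
  for (a in abbrev) {
    masked <- gsub(paste0("\\b(", a, ")\\."), "\\1<DOT>", masked, perl = TRUE)
  }
  parts <- strsplit(masked, "(?<=[.!?])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  parts <- gsub("<DOT>", ".", parts, fixed = TRUE)
  compact_chr(parts)
}

# Render sentences with their 0-based ids, one per line: "0. <sentence>"
number_sentences <- function(sentences) {
  paste(sprintf("%d. %s", seq_along(sentences) - 1L, sentences),
        collapse = "\n")
}
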