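#' Eligibility label sets
#'
#' Criterion-level eligibility uses different four-value label sets for
#' inclusion and exclusion criteria. Inclusion criteria are labelled
#' `included` / `not_included` / `not_enough_information` / `not_applicable`;
#' exclusion criteria are labelled `excluded` / `not_excluded` /
#' `not_enough_information` / `not_applicable`. Separate sets are used because
#' exclusion criteria are frequently phrased ambiguously ("Pregnancy",
#' "Pregnant patients will be excluded"), which plain entailment labels do not
#' capture.
#'
#' @param criterion_type `"inclusion"` or `"exclusion"`.
#' @return Character vector of the four valid labels for that criterion type.
#' @export
#' @examples
#' eligibility_labels("inclusion")
#' eligibility_labels("exclusion")
eligibility_labels <- function(criterion_type = c("inclusion", "exclusion")) {
  criterion_type <- match.arg(criterion_type)
  if (criterion_type == "inclusion") {
    c("included", "not_included", "not_enough_information", "not_applicable")
  } else {
    c("excluded", "not_excluded", "not_enough_information", "not_applicable")
  }
}

# canonicalise a label string: lowercase, spaces/hyphens -> underscores
normalise_label <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(x)))
}

validate_label <- function(label, criterion_type, criterion_index = NULL) {
  lab <- normalise_label(label)
  valid <- eligibility_labels(criterion_type)
  bad <- !(lab %in% valid)
  if (any(bad)) {
    where <- if (!is.null(criterion_index)) {
      sprintf(" at criterion index %s", paste(criterion_index[bad], collapse = ", "))
    } else ""
    abort(sprintf(
      "Invalid %s-criterion label%s: %s. Valid labels: %s.",
      criterion_type, where, paste(unique(label[bad]), collapse = ", "),
      paste(valid, collapse = ", ")
    ), class = "trialmatchr_validation_error")
  }
  lab
}

#' Cohort eligibility labels and their graded relevance
#'
#' Trial-level judgments use up to five labels across cohorts: `irrelevant`,
#' `potential` (consider referring upon further investigation), `excluded`
#' (has the target condition but an exclusion criterion applies), `eligible`,
#' and `unlabeled` for pairs outside the pooled judgments. For graded-relevance
#' evaluation these collapse to 0 (`irrelevant`, `unlabeled`), 1 (`excluded`,
#' `potential`), and 2 (`eligible`).
#'
#' @param cohort_label Character vector of cohort labels.
#' @return Integer vector of relevance grades (0, 1, or 2).
#' @export
#' @examples
#' relevance_of(c("eligible", "potential", "excluded", "irrelevant", "unlabeled"))
relevance_of <- function(cohort_label) {
  lab <- normalise_label(cohort_label)
  valid <- c("irrelevant", "potential", "excluded", "eligible", "unlabeled")
  bad <- !(lab %in% valid)
  if (any(bad)) {
    abort(sprintf("Unknown cohort label(s): %s. Valid labels: %s.",
                  paste(unique(cohort_label[bad]), collapse = ", "),
                  paste(valid, collapse = ", ")),
          class = "trialmatchr_validation_error")
  }
  unname(c(irrelevant = 0L, unlabeled = 0L, potential = 1L,
           excluded = 1L, eligible = 2L)[lab])
}
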