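# Trial-level aggregation of criterion-level results: six linear percentage
# scores, LLM-aggregated relevance/eligibility scores with their clamping
# constraints, the combined feature score, task-aware sign conventions for
# ranking vs excluding, and adapters for generic NLI-style predictors.

#' Linear aggregation of criterion-level results for one pair
#'
#' Computes the six percentage scores of one (patient, trial) pair.
#' With `M` inclusion criteria, the applicable count is
#' `M' = M - #not_applicable`; the met / unmet / no-information percentages
#' are the respective label counts divided by `M'` (analogously `N'` for
#' exclusion criteria). When `M'` (or `N'`) is 0 all three corresponding
#' percentages are defined as 0 and a degenerate flag is set.
#'
#' @param results Criterion-level tibble for a single pair (columns
#'   `criterion_type`, `label`).
#' @return One-row tibble with the six percentages, counts `n_inclusion`,
#'   `n_inclusion_applicable`, `n_exclusion`, `n_exclusion_applicable`, and
#'   `degenerate_inclusion` / `degenerate_exclusion` flags.
#' @export
#' @examples
#' res <- tibble::tibble(
#'   criterion_type = c("inclusion", "inclusion", "inclusion", "inclusion"),
#'   label = c("included", "included", "not_included", "not_applicable"))
#' linear_aggregate(res)
linear_aggregate <- function(results) {
  assert_columns(results, c("criterion_type", "label"), "results")
  side <- function(type) {
    lab <- results$label[results$criterion_type == type]
    met_lab <- if (type == "inclusion") "included" else "excluded"
    unmet_lab <- if (type == "inclusion") "not_included" else "not_excluded"
    n <- length(lab)
    n_app <- n - sum(lab == "not_applicable")
    denom <- if (n_app > 0) n_app else 1 # percentages defined as 0 when n_app == 0
    list(n = n, n_app = n_app, degenerate = n_app == 0,
         met = sum(lab == met_lab) / denom,
         unmet = sum(lab == unmet_lab) / denom,
         noinfo = sum(lab == "not_enough_information") / denom)
  }
  inc <- side("inclusion"); exc <- side("exclusion")
  tibble(
    pct_met_inclusion = inc$met, pct_unmet_inclusion = inc$unmet,
    pct_noinfo_inclusion = inc$noinfo,
    pct_met_exclusion = exc$met, pct_unmet_exclusion = exc$unmet,
    pct_noinfo_exclusion = exc$noinfo,
    n_inclusion = inc$n, n_inclusion_applicable = inc$n_app,
    n_exclusion = exc$n, n_exclusion_applicable = exc$n_app,
    degenerate_inclusion = inc$degenerate,
    degenerate_exclusion = exc$degenerate
  )
}

render_aggregation_prompt <- function(results) {
  expl <- results[["explanation"]] %||% rep("", nrow(results))
  lines <- sprintf("- [%s %d] %s (evidence sentences: %s): %s",
                   results$criterion_type, results$criterion_index,
                   gsub("_", " ", results$label),
                   vapply(results$sentence_ids,
                          function(x) if (length(x) == 0) "none" else
                            paste(x, collapse = ","), character(1)),
                   expl)
  paste0(
    "Given the criterion-level eligibility assessment below, rate the ",
    "patient-trial pair with two numbers: \"relevance\" between 0 (the ",
    "patient is irrelevant to the trial) and 100 (exactly relevant), and ",
    "\"eligibility\" between -relevance (definitely ineligible) and ",
    "+relevance (definitely eligible). Respond with a JSON object ",
    "{\"relevance\": ..., \"eligibility\": ...} only.\n\n",
    "Criterion-level assessment:\n", paste(lines, collapse = "\n"), "\n"
  )
}

#' LLM aggregation of criterion-level results for one pair
#'
#' Sends the serialized criterion-level predictions to the backend and parses
#' the two aggregate scores: general relevance `R` in `[0, 100]` (0 =
#' irrelevant, 100 = exactly relevant) and eligibility `S` constrained to
#' `[-R, R]` — the absolute eligibility cannot exceed the relevance. Values
#' outside those ranges are clamped and the clamping is reported.
#'
#' @param results Criterion-level tibble for a single pair (must carry
#'   `patient_id` and `trial_id` columns).
#' @param backend An [llm_backend()].
#' @return One-row tibble with `llm_relevance`, `llm_eligibility`, `clamped`.
#' @export
llm_aggregate <- function(results, backend) {
  assert_columns(results, c("patient_id", "trial_id", "criterion_type",
                            "criterion_index", "label"), "results")
  raw <- backend_call(backend, list(
    type = "aggregation", prompt = render_aggregation_prompt(results),
    patient_id = results$patient_id[[1]], trial_id = results$trial_id[[1]]
  ))
  parsed <- tryCatch(jsonlite::fromJSON(strip_code_fence(raw)),
                     error = function(e) e)
  r <- suppressWarnings(as.numeric(parsed$relevance %||% NA))
  s <- suppressWarnings(as.numeric(parsed$eligibility %||% NA))
  if (inherits(parsed, "error") || is.na(r) || is.na(s)) {
    abort("Aggregation output is not numeric relevance/eligibility JSON.",
          class = "trialmatchr_parse_error", raw_output = raw)
  }
  clamped <- FALSE
  if (r < 0 || r > 100) {
    r <- min(max(r, 0), 100); clamped <- TRUE
  }
  if (abs(s) > r) {
    s <- sign(s) * r; clamped <- TRUE
  }
  if (clamped) {
    inform(sprintf("Clamped aggregation scores for pair (%s, %s) to R=%g, S=%g.",
                   results$patient_id[[1]], results$trial_id[[1]], r, s),
           class = "trialmatchr_clamp_message")
  }
  tibble(llm_relevance = r, llm_eligibility = s, clamped = clamped)
}

#' Combine linear and LLM aggregation features
#'
#' `combined = %met_inclusion - I(%unmet_inclusion > 0) -
#' I(%met_exclusion > 0) + R/normalization + S/normalization`, where `I` is
#' the indicator function and `normalization` (default 100) puts the two LLM
#' scores on the same scale as the percentage features. The result lies in
#' `[-3, 3]`.
#'
#' @param pct_met_inclusion,pct_unmet_inclusion,pct_met_exclusion Linear
#'   percentages in `[0, 1]`.
#' @param llm_relevance Relevance `R` in `[0, 100]`.
#' @param llm_eligibility Eligibility `S` in `[-R, R]`.
#' @param normalization Divisor applied to the LLM scores (default 100).
#' @return Numeric combined score (vectorised).
#' @export
#' @examples
#' combine_features(1, 0, 0, 100, 100) # 3
combine_features <- function(pct_met_inclusion, pct_unmet_inclusion,
                             pct_met_exclusion, llm_relevance,
                             llm_eligibility, normalization = 100) {
  assert_scalar_number(normalization, "normalization", min = 1e-12)
  pct_met_inclusion -
    as.numeric(pct_unmet_inclusion > 0) -
    as.numeric(pct_met_exclusion > 0) +
    llm_relevance / normalization +
    llm_eligibility / normalization
}

#' Score all matched pairs at the trial level
#'
#' Applies [linear_aggregate()] to every (patient, trial) group of a
#' criterion-level result tibble, optionally adds the LLM aggregation via the
#' backend, and computes the combined feature score.
#'
#' @param matches Criterion-level tibble (e.g. `match_candidates()$results`).
#' @param backend An [llm_backend()] for the LLM aggregation, or `NULL` for
#'   linear-only scoring (LLM columns become `NA` and `combined` is not
#'   computed).
#' @param normalization Divisor for the LLM scores in the combination.
#' @return Trial-score tibble, one row per pair.
#' @export
score_trials <- function(matches, backend = NULL, normalization = 100) {
  assert_columns(matches, c("patient_id", "trial_id", "criterion_type",
                            "label"), "matches")
  key <- paste(matches$patient_id, matches$trial_id, sep = "\r")
  groups <- split(seq_len(nrow(matches)), factor(key, levels = unique(key)))
  n <- length(groups)
  cols <- list(patient_id = character(n), trial_id = character(n),
               pct_met_inclusion = numeric(n), pct_unmet_inclusion = numeric(n),
               pct_noinfo_inclusion = numeric(n),
               pct_met_exclusion = numeric(n), pct_unmet_exclusion = numeric(n),
               pct_noinfo_exclusion = numeric(n),
               n_inclusion = integer(n), n_inclusion_applicable = integer(n),
               n_exclusion = integer(n), n_exclusion_applicable = integer(n),
               degenerate_inclusion = logical(n),
               degenerate_exclusion = logical(n),
               llm_relevance = rep(NA_real_, n),
               llm_eligibility = rep(NA_real_, n), clamped = rep(NA, n),
               combined = rep(NA_real_, n))
  for (g in seq_len(n)) {
    idx <- groups[[g]]
    type <- matches$criterion_type[idx]
    lab <- matches$label[idx]
    cols$patient_id[[g]] <- matches$patient_id[[idx[1]]]
    cols$trial_id[[g]] <- matches$trial_id[[idx[1]]]
    for (side in c("inclusion", "exclusion")) {
      sl <- lab[type == side]
      met_lab <- if (side == "inclusion") "included" else "excluded"
      unmet_lab <- if (side == "inclusion") "not_included" else "not_excluded"
      n_all <- length(sl)
      n_app <- n_all - sum(sl == "not_applicable")
      denom <- if (n_app > 0) n_app else 1
      sfx <- if (side == "inclusion") "inclusion" else "exclusion"
      cols[[paste0("pct_met_", sfx)]][[g]] <- sum(sl == met_lab) / denom
      cols[[paste0("pct_unmet_", sfx)]][[g]] <- sum(sl == unmet_lab) / denom
      cols[[paste0("pct_noinfo_", sfx)]][[g]] <-
        sum(sl == "not_enough_information") / denom
      cols[[paste0("n_", sfx)]][[g]] <- n_all
      cols[[paste0("n_", sfx, "_applicable")]][[g]] <- n_app
      cols[[paste0("degenerate_", sfx)]][[g]] <- n_app == 0L
    }
    if (!is.null(backend)) {
      llm <- llm_aggregate(matches[idx, ], backend)
      cols$llm_relevance[[g]] <- llm$llm_relevance
      cols$llm_eligibility[[g]] <- llm$llm_eligibility
      cols$clamped[[g]] <- llm$clamped
      cols$combined[[g]] <- combine_features(
        cols$pct_met_inclusion[[g]], cols$pct_unmet_inclusion[[g]],
        cols$pct_met_exclusion[[g]], llm$llm_relevance, llm$llm_eligibility,
        normalization)
    }
  }
  tibble::new_tibble(cols, nrow = n)
}

ranking_features <- c("met_inclusion", "unmet_inclusion", "met_exclusion",
                      "unmet_exclusion", "relevance", "eligibility",
                      "combined")

#' Task-oriented score for one feature
#'
#' Assigns the sign suitable for the task to a single aggregation feature.
#' For the ranking task (higher = more suitable trial) the natural signs are
#' `+%met_inclusion`, `-%unmet_inclusion`, `-%met_exclusion`,
#' `+%unmet_exclusion`, `+R`, `+S`, and `combined` as-is; for the excluding
#' task (higher = more likely explicitly ineligible) all signs are flipped.
#' LLM scores are divided by `normalization` so every feature is on a
#' comparable scale.
#'
#' @param scores Trial-score tibble from [score_trials()].
#' @param feature One of `"met_inclusion"`, `"unmet_inclusion"`,
#'   `"met_exclusion"`, `"unmet_exclusion"`, `"relevance"`, `"eligibility"`,
#'   `"combined"`.
#' @param task `"ranking"` or `"excluding"`.
#' @param normalization Divisor for the LLM scores.
#' @return Numeric vector of task scores, one per row of `scores`.
#' @export
task_score <- function(scores, feature = "combined",
                       task = c("ranking", "excluding"), normalization = 100) {
  task <- match.arg(task)
  if (!is.character(feature) || length(feature) != 1L ||
      !(feature %in% ranking_features)) {
    abort(sprintf("Unknown feature `%s`. Valid features: %s.",
                  paste(feature, collapse = ", "),
                  paste(ranking_features, collapse = ", ")),
          class = "trialmatchr_config_error")
  }
  base <- switch(feature,
    met_inclusion = scores$pct_met_inclusion,
    unmet_inclusion = -scores$pct_unmet_inclusion,
    met_exclusion = -scores$pct_met_exclusion,
    unmet_exclusion = scores$pct_unmet_exclusion,
    relevance = scores$llm_relevance / normalization,
    eligibility = scores$llm_eligibility / normalization,
    combined = scores$combined
  )
  if (task == "ranking") base else -base
}

#' Map NLI labels to eligibility labels
#'
#' Adapter for generic natural-language-inference predictors: `entailment`
#' maps to the criterion being met (`included` / `excluded`),
#' `contradiction` to it being unmet (`not_included` / `not_excluded`), and
#' `neutral` to `not_enough_information`.
#'
#' @param nli_label Character vector of `entailment` / `contradiction` /
#'   `neutral`.
#' @param criterion_type `"inclusion"` or `"exclusion"`.
#' @return Character vector of eligibility labels.
#' @export
#' @examples
#' map_nli_labels(c("entailment", "neutral"), "inclusion")
map_nli_labels <- function(nli_label, criterion_type = c("inclusion", "exclusion")) {
  criterion_type <- match.arg(criterion_type)
  lab <- normalise_label(nli_label)
  valid <- c("entailment", "contradiction", "neutral")
  if (any(!(lab %in% valid))) {
    abort(sprintf("Unknown NLI label(s): %s.",
                  paste(unique(nli_label[!(lab %in% valid)]), collapse = ", ")),
          class = "trialmatchr_validation_error")
  }
  mapping <- if (criterion_type == "inclusion") {
    c(entailment = "included", contradiction = "not_included",
      neutral = "not_enough_information")
  } else {
    c(entailment = "excluded", contradiction = "not_excluded",
      neutral = "not_enough_information")
  }
  unname(mapping[lab])
}

#' Criterion-percentage combination score for generic predictors
#'
#' The combination arithmetic used with NLI-adapted criterion predictions:
#' for ranking, `%met_inclusion - %unmet_inclusion - %met_exclusion +
#' %unmet_exclusion`; for excluding, `I(%unmet_inclusion > 0) +
#' I(%met_exclusion > 0) - %met_inclusion`.
#'
#' @param scores Trial-score tibble (needs the four percentage columns).
#' @param task `"ranking"` or `"excluding"`.
#' @return Numeric vector of combination scores.
#' @export
baseline_combination <- function(scores, task = c("ranking", "excluding")) {
  task <- match.arg(task)
  if (task == "ranking") {
    scores$pct_met_inclusion - scores$pct_unmet_inclusion -
      scores$pct_met_exclusion + scores$pct_unmet_exclusion
  } else {
    as.numeric(scores$pct_unmet_inclusion > 0) +
      as.numeric(scores$pct_met_exclusion > 0) -
      scores$pct_met_inclusion
  }
}

#' Rank candidate trials per patient by a task score
#'
#' Orders each patient's candidates by descending task score, breaking ties
#' by `trial_id` so that rankings are stable and deterministic. A
#' non-finite score is an error naming the offending pair.
#'
#' @param scores Trial-score tibble from [score_trials()].
#' @param feature,task,normalization Passed to [task_score()].
#' @param tag Run tag for the output.
#' @return Run tibble with `patient_id`, `trial_id`, `rank`, `score`, `tag`.
#' @export
rank_trials <- function(scores, feature = "combined",
                        task = c("ranking", "excluding"),
                        normalization = 100, tag = "trialmatchr") {
  task <- match.arg(task)
  assert_columns(scores, c("patient_id", "trial_id"), "scores")
  s <- task_score(scores, feature = feature, task = task,
                  normalization = normalization)
  bad <- !is.finite(s)
  if (any(bad)) {
    abort(sprintf("Non-finite %s score for pair(s): %s.", feature,
                  paste(sprintf("(%s, %s)", scores$patient_id[bad],
                                scores$trial_id[bad]), collapse = ", ")),
          class = "trialmatchr_validation_error")
  }
  tibble(patient_id = scores$patient_id, trial_id = scores$trial_id,
         score = s) |>
    arrange(.data$patient_id, desc(.data$score), .data$trial_id) |>
    group_by(.data$patient_id) |>
    mutate(rank = row_number(), tag = tag) |>
    ungroup() |>
    select("patient_id", "trial_id", "rank", "score", "tag")
}
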