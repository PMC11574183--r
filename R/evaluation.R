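# Graded-relevance evaluation: Recall@k for the retrieval stage, NDCG@k and
# graded P@k for ranking, and a tie-corrected Mann-Whitney AUROC for the
# excluding task. Unlabeled pairs count as relevance 0 for retrieval recall
# (pooled-judgment assumption) but are removed before the ranking and
# excluding metrics.

join_grades <- function(run, qrels) {
  assert_columns(run, c("patient_id", "trial_id", "rank"), "run")
  assert_columns(qrels, c("patient_id", "trial_id", "grade"), "qrels")
  unknown <- setdiff(unique(run$patient_id), unique(qrels$patient_id))
  if (length(unknown) > 0L) {
    abort(sprintf("Run references patient id(s) absent from qrels: %s.",
                  paste(unknown, collapse = ", ")),
          class = "trialmatchr_validation_error")
  }
  left_join(run, qrels, by = c("patient_id", "trial_id")) |>
    arrange(.data$patient_id, .data$rank)
}

#' Graded Recall@k
#'
#' For each patient, the sum of graded relevance over the top `k` retrieved
#' trials divided by the total relevance mass `R` of the patient's judged
#' collection (an eligible trial, grade 2, counts twice an excluded or
#' potential one, grade 1). Retrieved pairs without a judgment count as
#' grade 0. Patients with `R = 0` have no defined recall and get `NA`.
#'
#' @param run Run tibble (`patient_id`, `trial_id`, `rank`).
#' @param qrels Qrels tibble (`patient_id`, `trial_id`, `grade`).
#' @param k Retrieval depth.
#' @return Tibble with `patient_id` and `recall`.
#' @export
recall_at_k <- function(run, qrels, k) {
  assert_scalar_number(k, "k", min = 1)
  joined <- join_grades(run, qrels)
  joined$grade[is.na(joined$grade)] <- 0L
  totals <- qrels |>
    group_by(.data$patient_id) |>
    summarise(total = sum(.data$grade), .groups = "drop")
  joined |>
    filter(.data$rank <= k) |>
    group_by(.data$patient_id) |>
    summarise(got = sum(.data$grade), .groups = "drop") |>
    left_join(totals, by = "patient_id") |>
    mutate(recall = ifelse(.data$total > 0, .data$got / .data$total,
                           NA_real_)) |>
    select("patient_id", "recall")
}

dcg <- function(grades, k) {
  grades <- head(grades, k)
  if (length(grades) == 0L) return(0)
  sum(grades / log2(seq_along(grades) + 1))
}

#' NDCG@k over labeled pairs
#'
#' Unlabeled pairs are removed from the run first; the discounted cumulative
#' gain of the top `k` remaining trials (`sum r_x / log2(x + 1)`) is
#' normalised by the ideal DCG computed from *all* of the patient's labeled
#' trials sorted by decreasing relevance. Patients whose ideal DCG is 0 are
#' skipped with a warning (`NA`).
#'
#' @inheritParams recall_at_k
#' @param k Ranking depth (default 10).
#' @return Tibble with `patient_id` and `ndcg`.
#' @export
ndcg_at_k <- function(run, qrels, k = 10) {
  assert_scalar_number(k, "k", min = 1)
  joined <- join_grades(run, qrels) |> filter(!is.na(.data$grade))
  patients <- unique(run$patient_id)
  rows <- lapply(patients, function(p) {
    got <- joined$grade[joined$patient_id == p]
    ideal <- sort(qrels$grade[qrels$patient_id == p], decreasing = TRUE)
    idcg <- dcg(ideal, k)
    if (idcg == 0) {
      warn(sprintf("Patient %s has no relevant labeled trials; NDCG undefined.", p),
           class = "trialmatchr_metric_warning")
      return(tibble(patient_id = p, ndcg = NA_real_))
    }
    tibble(patient_id = p, ndcg = dcg(got, k) / idcg)
  })
  bind_rows(rows)
}

#' Graded precision at k
#'
#' Unlabeled pairs are removed from the run first; P@k is the sum of the top
#' `k` relevance grades divided by `max_grade * k` (maximum grade 2), so a
#' top-10 of all-eligible trials scores 1 and all-grade-1 trials score 0.5.
#'
#' @inheritParams ndcg_at_k
#' @param max_grade Maximum relevance grade (default 2).
#' @return Tibble with `patient_id` and `precision`.
#' @export
precision_at_k <- function(run, qrels, k = 10, max_grade = 2) {
  assert_scalar_number(k, "k", min = 1)
  joined <- join_grades(run, qrels) |> filter(!is.na(.data$grade))
  joined |>
    group_by(.data$patient_id) |>
    summarise(precision = sum(head(.data$grade, k)) / (max_grade * k),
              .groups = "drop")
}

#' Area under the ROC curve (rank-based, tie-corrected)
#'
#' The Mann-Whitney formulation: the probability that a randomly chosen
#' positive receives a higher score than a randomly chosen negative, with
#' ties counted half. Computed from mid-ranks, so it is invariant under any
#' strictly monotone transform of the scores and equals 0.5 when all scores
#' are tied. Undefined (`NA`, with a warning) when only one class is present.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical, or 0/1).
#' @return AUROC in `[0, 1]`, or `NA` if undefined.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    warn("AUROC undefined: only one class present.",
         class = "trialmatchr_metric_warning")
    return(NA_real_)
  }
  r <- rank(scores) # mid-ranks give the tie correction
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

parse_metric_spec <- function(metrics) {
  lapply(metrics, function(m) {
    m <- tolower(trimws(m))
    if (m == "auroc") return(list(name = "auroc", fun = "auroc", k = NA))
    parts <- strsplit(m, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !(parts[1] %in% c("recall", "ndcg", "p")) ||
        is.na(suppressWarnings(as.integer(parts[2])))) {
      abort(sprintf("Unknown metric spec `%s`.", m),
            class = "trialmatchr_config_error")
    }
    list(name = m, fun = parts[1], k = as.integer(parts[2]))
  })
}

#' Evaluate a run against relevance judgments
#'
#' Computes the requested metrics per patient plus their unweighted
#' (macro) mean. AUROC is computed once over all labeled pairs pooled across
#' patients: the positive class is the explicitly ineligible label — rows
#' where the qrels carry `cohort_label == positive_label` if that column is
#' present, otherwise grade-1 rows — and the score is the run's `score`
#' column (use an excluding-task run for this metric).
#'
#' @param run Run tibble (`patient_id`, `trial_id`, `rank`, `score`).
#' @param qrels Qrels tibble, optionally with a `cohort_label` column.
#' @param metrics Character vector, e.g.
#'   `c("recall@500", "ndcg@10", "p@10", "auroc")`.
#' @param positive_label Cohort label treated as the positive (ineligible)
#'   class for AUROC.
#' @return A `trial_eval` object; see [tidy()] and [glance()] methods.
#' @export
evaluate_run <- function(run, qrels,
                         metrics = c("ndcg@10", "p@10"),
                         positive_label = "excluded") {
  specs <- parse_metric_spec(metrics)
  per_patient <- list(); pooled <- list()
  for (spec in specs) {
    if (spec$fun == "auroc") {
      joined <- join_grades(run, qrels) |> filter(!is.na(.data$grade))
      pos <- if ("cohort_label" %in% names(joined)) {
        normalise_label(joined$cohort_label) == normalise_label(positive_label)
      } else joined$grade == 1L
      pooled[[spec$name]] <- auroc(joined$score, pos)
      next
    }
    vals <- switch(spec$fun,
      recall = recall_at_k(run, qrels, spec$k) |>
        dplyr::rename(value = "recall"),
      ndcg = ndcg_at_k(run, qrels, spec$k) |> dplyr::rename(value = "ndcg"),
      p = precision_at_k(run, qrels, spec$k) |>
        dplyr::rename(value = "precision"))
    per_patient[[spec$name]] <- mutate(vals, metric = spec$name)
  }
  per_patient <- bind_rows(per_patient)
  summary <- if (nrow(per_patient) > 0) {
    per_patient |>
      group_by(.data$metric) |>
      summarise(mean = mean(.data$value, na.rm = TRUE),
                n_patients = sum(!is.na(.data$value)), .groups = "drop")
  } else {
    tibble(metric = character(), mean = numeric(), n_patients = integer())
  }
  if (length(pooled) > 0) {
    summary <- bind_rows(summary, tibble(
      metric = names(pooled), mean = unname(unlist(pooled)),
      n_patients = length(unique(run$patient_id))))
  }
  structure(list(per_patient = per_patient, summary = summary,
                 metrics = metrics),
            class = "trial_eval")
}

#' @export
print.trial_eval <- function(x, ...) {
  cat("<trial_eval>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname evaluate_run
#' @param x A `trial_eval` object.
#' @param ... Unused.
#' @export
tidy.trial_eval <- function(x, ...) {
  x$per_patient[, c("patient_id", "metric", "value")]
}

#' @rdname evaluate_run
#' @export
glance.trial_eval <- function(x, ...) {
  wide <- as.list(setNames(x$summary$mean, x$summary$metric))
  as_tibble(wide)
}

#' @rdname evaluate_run
#' @param object A `trial_eval` object.
#' @export
autoplot.trial_eval <- function(object, ...) {
  df <- object$per_patient
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "per-patient metric value") +
    ggplot2::theme_minimal()
}

#' Recall curve across retrieval depths
#'
#' Macro-averaged graded recall at each requested depth; useful for choosing
#' the candidate-list size of the first retrieval stage.
#'
#' @inheritParams recall_at_k
#' @param ks Integer vector of depths.
#' @return A tibble of class `recall_curve` with `k` and `recall`.
#' @export
recall_curve <- function(run, qrels, ks = c(10, 20, 50, 100, 200, 500)) {
  rows <- lapply(ks, function(k) {
    r <- recall_at_k(run, qrels, k)
    tibble(k = k, recall = mean(r$recall, na.rm = TRUE))
  })
  structure(bind_rows(rows), class = c("recall_curve", "tbl_df", "tbl",
                                       "data.frame"))
}

#' @rdname recall_curve
#' @param object A `recall_curve` tibble.
#' @param ... Unused.
#' @export
autoplot.recall_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$recall)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "retrieval depth k", y = "graded recall@k") +
    ggplot2::theme_minimal()
}

#' Criterion-level accuracy against reference labels
#'
#' Joins predicted and reference criterion-level tibbles on
#' (patient, trial, criterion type, criterion index) and reports label
#' accuracy.
#'
#' @param predicted,reference Criterion-level tibbles with a `label` column.
#' @return One-row tibble with `accuracy` and `n` compared criteria.
#' @export
criterion_accuracy <- function(predicted, reference) {
  keys <- c("patient_id", "trial_id", "criterion_type", "criterion_index")
  joined <- dplyr::inner_join(
    predicted[, c(keys, "label")],
    dplyr::rename(reference[, c(keys, "label")], label_true = "label"),
    by = keys)
  tibble(accuracy = mean(joined$label == joined$label_true),
         n = nrow(joined))
}

#' Evidence-sentence precision and recall
#'
#' Micro-averaged over the criteria that have at least one reference relevant
#' sentence: precision is the fraction of predicted sentence IDs that are in
#' the reference set, recall the fraction of reference IDs that were
#' predicted.
#'
#' @param predicted,reference Criterion-level tibbles with a `sentence_ids`
#'   list column.
#' @return One-row tibble with `precision`, `recall`, `f1`, and `n` criteria
#'   considered.
#' @export
evidence_metrics <- function(predicted, reference) {
  keys <- c("patient_id", "trial_id", "criterion_type", "criterion_index")
  joined <- dplyr::inner_join(
    predicted[, c(keys, "sentence_ids")],
    dplyr::rename(reference[, c(keys, "sentence_ids")],
                  sentence_ids_true = "sentence_ids"),
    by = keys)
  joined <- joined[lengths(joined$sentence_ids_true) > 0L, ]
  tp <- sum(map_int(seq_len(nrow(joined)), function(i) {
    length(intersect(joined$sentence_ids[[i]], joined$sentence_ids_true[[i]]))
  }))
  n_pred <- sum(lengths(joined$sentence_ids))
  n_true <- sum(lengths(joined$sentence_ids_true))
  precision <- if (n_pred > 0) tp / n_pred else NA_real_
  recall <- if (n_true > 0) tp / n_true else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble(precision = precision, recall = recall, f1 = f1, n = nrow(joined))
}
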