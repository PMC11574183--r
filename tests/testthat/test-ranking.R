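crit_tbl <- function(inclusion = character(), exclusion = character(),
                     patient_id = "p", trial_id = "t") {
  tibble::tibble(
    patient_id = patient_id, trial_id = trial_id,
    criterion_type = c(rep("inclusion", length(inclusion)),
                       rep("exclusion", length(exclusion))),
    criterion_index = c(seq_along(inclusion), seq_along(exclusion)) - 1L,
    explanation = "", sentence_ids = list(integer()),
    label = c(inclusion, exclusion))
}

test_that("linear aggregation counts percentages over applicable criteria", {
  lin <- linear_aggregate(crit_tbl(
    inclusion = c("included", "included", "not_included", "not_applicable")))
  expect_identical(lin$n_inclusion_applicable, 3L)
  expect_equal(lin$pct_met_inclusion, 2 / 3)
  expect_equal(lin$pct_unmet_inclusion, 1 / 3)
  expect_equal(lin$pct_noinfo_inclusion, 0)

  lin2 <- linear_aggregate(crit_tbl(
    exclusion = c("excluded", "not_enough_information")))
  expect_identical(lin2$n_exclusion_applicable, 2L)
  expect_equal(lin2$pct_met_exclusion, 1 / 2)
  expect_equal(lin2$pct_noinfo_exclusion, 1 / 2)

  degen <- linear_aggregate(crit_tbl(
    inclusion = c("not_applicable", "not_applicable")))
  expect_true(degen$degenerate_inclusion)
  expect_equal(degen$pct_met_inclusion + degen$pct_unmet_inclusion +
                 degen$pct_noinfo_inclusion, 0)
})

test_that("percentage triples sum to one whenever criteria are applicable", {
  withr::local_seed(5)
  for (i in 1:50) {
    inc <- sample(eligibility_labels("inclusion"), sample(1:8, 1),
                  replace = TRUE)
    exc <- sample(eligibility_labels("exclusion"), sample(0:8, 1),
                  replace = TRUE)
    lin <- linear_aggregate(crit_tbl(inclusion = inc, exclusion = exc))
    if (lin$n_inclusion_applicable > 0) {
      expect_equal(lin$pct_met_inclusion + lin$pct_unmet_inclusion +
                     lin$pct_noinfo_inclusion, 1)
    }
    if (lin$n_exclusion_applicable > 0) {
      expect_equal(lin$pct_met_exclusion + lin$pct_unmet_exclusion +
                     lin$pct_noinfo_exclusion, 1)
    }
  }
})

test_that("LLM aggregation clamps relevance and eligibility as specified", {
  tbl <- crit_tbl(inclusion = "included")
  over <- scripted_backend(list(
    aggregation = '{"relevance": 110, "eligibility": 40}'))
  expect_message(r1 <- llm_aggregate(tbl, over),
                 class = "trialmatchr_clamp_message")
  expect_equal(r1$llm_relevance, 100)
  expect_equal(r1$llm_eligibility, 40)
  expect_true(r1$clamped)

  neg <- scripted_backend(list(
    aggregation = '{"relevance": 30, "eligibility": -50}'))
  expect_message(r2 <- llm_aggregate(tbl, neg),
                 class = "trialmatchr_clamp_message")
  expect_equal(unlist(r2[, c("llm_relevance", "llm_eligibility")]),
               c(llm_relevance = 30, llm_eligibility = -30))

  ok <- scripted_backend(list(
    aggregation = '{"relevance": 80, "eligibility": -20}'))
  r3 <- llm_aggregate(tbl, ok)
  expect_false(r3$clamped)

  junk <- scripted_backend(list(aggregation = "no numbers here"))
  expect_error(llm_aggregate(tbl, junk), class = "trialmatchr_parse_error")
})

test_that("oracle aggregation of a fully eligible pair returns (100, 100)", {
  co <- shared_cohort()
  be <- mock_backend(co, noise = 0, seed = 1)
  elig <- co$qrels[co$qrels$cohort_label == "eligible", ][1, ]
  truth <- co$criterion_truth[
    co$criterion_truth$patient_id == elig$patient_id &
      co$criterion_truth$trial_id == elig$trial_id, ]
  r <- llm_aggregate(truth, be)
  expect_equal(r$llm_relevance, 100)
  expect_equal(r$llm_eligibility, 100)
})

test_that("feature combination matches direct substitution and is monotone", {
  expect_equal(combine_features(1, 0, 0, 100, 100), 3)
  expect_equal(combine_features(0.5, 0.25, 0.5, 40, -40), -1.5)
  expect_equal(combine_features(0, 0, 0, 0, 0), 0)
  # monotone: non-decreasing in met%, R, S; non-increasing via the indicators
  base <- combine_features(0.5, 0, 0, 50, 10)
  expect_gt(combine_features(0.6, 0, 0, 50, 10), base)
  expect_gt(combine_features(0.5, 0, 0, 60, 10), base)
  expect_gt(combine_features(0.5, 0, 0, 50, 20), base)
  expect_lt(combine_features(0.5, 0.1, 0, 50, 10), base)
  expect_lt(combine_features(0.5, 0, 0.1, 50, 10), base)
})

test_that("task scores carry the sign convention for ranking and excluding", {
  scores <- tibble::tibble(
    patient_id = "p", trial_id = "t",
    pct_met_inclusion = 0.8, pct_unmet_inclusion = 0.2,
    pct_met_exclusion = 0.5, pct_unmet_exclusion = 0.5,
    llm_relevance = 70, llm_eligibility = -100, combined = 3)
  expect_equal(task_score(scores, "met_inclusion", "excluding"), -0.8)
  expect_equal(task_score(scores, "met_inclusion", "ranking"), 0.8)
  expect_equal(task_score(scores, "unmet_inclusion", "ranking"), -0.2)
  expect_equal(task_score(scores, "met_exclusion", "ranking"), -0.5)
  expect_equal(task_score(scores, "unmet_exclusion", "ranking"), 0.5)
  expect_equal(task_score(scores, "eligibility", "ranking"), -1.0)
  expect_equal(task_score(scores, "relevance", "ranking"), 0.7)
  expect_equal(task_score(scores, "combined", "ranking"), 3)
  expect_equal(task_score(scores, "combined", "excluding"), -3)
  expect_error(task_score(scores, "unknown", "ranking"),
               class = "trialmatchr_config_error")
})

test_that("NLI labels map onto the eligibility label spaces", {
  expect_identical(map_nli_labels("entailment", "inclusion"), "included")
  expect_identical(map_nli_labels("contradiction", "inclusion"),
                   "not_included")
  expect_identical(map_nli_labels("neutral", "inclusion"),
                   "not_enough_information")
  expect_identical(map_nli_labels("entailment", "exclusion"), "excluded")
  expect_identical(map_nli_labels("contradiction", "exclusion"),
                   "not_excluded")
  expect_identical(map_nli_labels("neutral", "exclusion"),
                   "not_enough_information")
  expect_error(map_nli_labels("maybe", "inclusion"),
               class = "trialmatchr_validation_error")
})

test_that("criterion-percentage combination scores match hand computation", {
  all_met <- tibble::tibble(pct_met_inclusion = 1, pct_unmet_inclusion = 0,
                            pct_met_exclusion = 0, pct_unmet_exclusion = 1)
  expect_equal(baseline_combination(all_met, "ranking"), 2)
  mix <- tibble::tibble(pct_met_inclusion = 0.1, pct_unmet_inclusion = 0.2,
                        pct_met_exclusion = 0.3, pct_unmet_exclusion = 0)
  expect_equal(baseline_combination(mix, "excluding"), 1.9)
  zero <- tibble::tibble(pct_met_inclusion = 0, pct_unmet_inclusion = 0,
                         pct_met_exclusion = 0, pct_unmet_exclusion = 0)
  expect_equal(baseline_combination(zero, "ranking"), 0)
  expect_equal(baseline_combination(zero, "excluding"), 0)
})

test_that("the excluding combination separates eligible from excluded pairs", {
  co <- shared_cohort()
  s <- score_trials(co$criterion_truth) # linear-only on true labels
  s <- dplyr::inner_join(s, co$qrels, by = c("patient_id", "trial_id"))
  sub <- s[s$cohort_label %in% c("eligible", "excluded"), ]
  val <- baseline_combination(sub, "excluding")
  expect_equal(auroc(val, sub$cohort_label == "excluded"), 1)
})

test_that("trial ranking is deterministic with ties broken by id", {
  scores <- tibble::tibble(
    patient_id = "p", trial_id = c("B", "A", "C"),
    pct_met_inclusion = 0, pct_unmet_inclusion = 0, pct_met_exclusion = 0,
    pct_unmet_exclusion = 0, llm_relevance = 0, llm_eligibility = 0,
    combined = c(-1.5, 3, 3))
  r <- rank_trials(scores, feature = "combined")
  expect_identical(r$trial_id, c("A", "C", "B"))
  expect_identical(r$rank, 1:3)
  single <- rank_trials(scores[1, ], feature = "combined")
  expect_identical(single$trial_id, "B")

  scores$combined[2] <- NaN
  err <- expect_error(rank_trials(scores, feature = "combined"),
                      class = "trialmatchr_validation_error")
  expect_match(conditionMessage(err), "\\(p, A\\)")
})
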