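make_note <- function(text = "Has diabetes. Takes insulin daily. Age is 54. Blood pressure is normal. Sleeps well.") {
  as_patient_notes(tibble::tibble(patient_id = "p1", text = text))
}

test_that("matching prompts number criteria and sentences from 0 and quote the label sets", {
  corp <- as_trial_corpus(tiny_corpus())
  trial <- corp[1, ]
  trial$inclusion_criteria <- list(c("Diagnosis of diabetes.",
                                     "Age over 18.", "On stable therapy."))
  note <- make_note()
  p <- build_matching_prompt(note, trial, "inclusion")
  expect_identical(p$n_criteria, 3L)
  expect_match(p$rendered_text, "0\\. Diagnosis of diabetes\\.")
  expect_match(p$rendered_text, "2\\. On stable therapy\\.")
  expect_match(p$rendered_text,
               "included, not included, not enough information, not applicable")
  # note with 5 sentences renders ids 0..4
  expect_identical(p$n_sentences, 5L)
  expect_match(p$rendered_text, "\n4\\. Sleeps well\\.")

  pe <- build_matching_prompt(note, trial, "exclusion")
  expect_match(pe$rendered_text,
               "excluded, not excluded, not enough information, not applicable")
  # zero criteria of a type is a skip signal
  none <- trial; none$exclusion_criteria <- list(character())
  expect_error(build_matching_prompt(note, none, "exclusion"),
               class = "trialmatchr_empty_criteria")
})

test_that("well-formed structured output round-trips losslessly", {
  raw <- jsonlite::toJSON(list(
    "0" = list(explanation = "matches", sentence_ids = list(0L, 1L),
               label = "included"),
    "1" = list(explanation = "nothing stated", sentence_ids = list(),
               label = "not enough information")), auto_unbox = TRUE)
  res <- parse_matching_output(raw, "inclusion", 2L, 5L)
  expect_identical(res$label, c("included", "not_enough_information"))
  expect_identical(res$sentence_ids, list(c(0L, 1L), integer()))
  expect_false(any(res$imputed))
  # serialize -> parse again is identical
  back <- jsonlite::toJSON(setNames(lapply(seq_len(nrow(res)), function(i) {
    list(explanation = res$explanation[[i]],
         sentence_ids = as.list(res$sentence_ids[[i]]),
         label = res$label[[i]])
  }), as.character(res$criterion_index)), auto_unbox = TRUE)
  expect_identical(parse_matching_output(back, "inclusion", 2L, 5L), res)
})

test_that("out-of-range sentence ids are dropped with a warning", {
  raw <- '{"0": {"explanation": "x", "sentence_ids": [1, 8, 1], "label": "included"}}'
  expect_warning(res <- parse_matching_output(raw, "inclusion", 1L, 5L),
                 class = "trialmatchr_sentence_id_warning")
  expect_identical(res$sentence_ids[[1]], 1L) # deduplicated and filtered
})

test_that("wrong-type labels and unparseable output raise typed errors", {
  wrong <- '{"0": {"explanation": "x", "sentence_ids": [], "label": "included"}}'
  err <- expect_error(parse_matching_output(wrong, "exclusion", 1L, 5L),
                      class = "trialmatchr_validation_error")
  expect_match(conditionMessage(err), "criterion index 0")

  bad <- '{"0": {"explanation": "trunc'
  err2 <- expect_error(parse_matching_output(bad, "inclusion", 1L, 5L),
                       class = "trialmatchr_parse_error")
  expect_identical(err2$raw_output, bad)
})

test_that("missing criteria are filled with a flagged sentinel", {
  raw <- '{"0": {"explanation": "x", "sentence_ids": [0], "label": "excluded"}}'
  res <- parse_matching_output(raw, "exclusion", 3L, 5L)
  expect_identical(nrow(res), 3L)
  expect_identical(res$label[2:3], rep("not_enough_information", 2))
  expect_identical(res$imputed, c(FALSE, TRUE, TRUE))
})

test_that("match_trial covers every criterion and skips empty criterion lists", {
  co <- shared_cohort()
  be <- mock_backend(co, noise = 0, seed = 1)
  trial <- co$corpus[1, ]
  note <- co$patients[1, ]
  m <- match_trial(note, trial, be)
  expect_s3_class(m, "trial_match")
  expect_identical(sum(m$results$criterion_type == "inclusion"),
                   length(trial$inclusion_criteria[[1]]))
  expect_identical(sum(m$results$criterion_type == "exclusion"),
                   length(trial$exclusion_criteria[[1]]))
  expect_identical(sort(names(m$raw_outputs)),
                   sort(c("inclusion",
                          "exclusion")[c(TRUE, length(trial$exclusion_criteria[[1]]) > 0)]))

  # a trial with no exclusion criteria triggers exactly one backend call
  no_excl <- trial
  no_excl$exclusion_criteria <- list(character())
  cb <- counting_backend(be)
  m2 <- match_trial(note, no_excl, cb$backend)
  expect_identical(cb$calls$n, 1L)
  expect_identical(unique(m2$results$criterion_type), "inclusion")
})

test_that("oracle matching reproduces the ground truth exactly and deterministically", {
  co <- shared_cohort()
  be <- mock_backend(co, noise = 0, seed = 1)
  cand <- co$qrels[co$qrels$patient_id == co$patients$patient_id[[1]], ][1:25, ]
  b1 <- match_candidates(cand, co$patients, co$corpus, be)
  expect_identical(nrow(b1$failures), 0L)
  acc <- criterion_accuracy(b1$results, co$criterion_truth)
  expect_equal(acc$accuracy, 1)
  # coverage: one result per criterion of every processed pair
  per_pair <- dplyr::count(b1$results, patient_id, trial_id)
  truth_pair <- dplyr::count(
    dplyr::semi_join(co$criterion_truth, cand,
                     by = c("patient_id", "trial_id")),
    patient_id, trial_id)
  expect_equal(dplyr::arrange(per_pair, trial_id),
               dplyr::arrange(truth_pair, trial_id))

  # determinism: a repeat run and a zero-noise noisy oracle are identical
  b2 <- match_candidates(cand, co$patients, co$corpus, be)
  expect_identical(b1$results, b2$results)
  b3 <- match_candidates(cand, co$patients, co$corpus,
                         mock_backend(co, noise = 0, seed = 99))
  expect_identical(b1$results, b3$results)
})

test_that("faulty backends fail pairs without aborting the batch", {
  co <- shared_cohort()
  cand <- co$qrels[co$qrels$patient_id == co$patients$patient_id[[1]], ][1:6, ]

  corrupted <- mock_backend(co, mode = "corrupted")
  b <- match_candidates(cand, co$patients, co$corpus, corrupted)
  expect_identical(nrow(b$failures), nrow(cand))
  expect_identical(nrow(b$results), 0L)

  wrong <- mock_backend(co, mode = "wrong_label")
  bw <- match_candidates(cand, co$patients, co$corpus, wrong)
  # pairs with exclusion criteria fail label validation; the rest succeed
  has_excl <- vapply(cand$trial_id, function(t) {
    length(co$corpus$exclusion_criteria[[match(t, co$corpus$trial_id)]]) > 0
  }, logical(1))
  expect_identical(nrow(bw$failures), sum(has_excl))
  expect_true(all(grepl("criterion index", bw$failures$error)))

  oor <- mock_backend(co, mode = "out_of_range")
  w <- testthat::capture_warnings(
    bo <- match_candidates(cand[1, ], co$patients, co$corpus, oor))
  expect_true(all(grepl("out-of-range sentence id", w)))
  expect_gt(length(w), 0L)
  expect_identical(nrow(bo$failures), 0L)
  # the oversized ids were dropped, valid ones kept
  n_sent <- lengths(co$patients$sentences)[
    match(cand$patient_id[1], co$patients$patient_id)]
  expect_true(all(unlist(bo$results$sentence_ids) < n_sent))
})
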