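# Synthetic cohort simulator: a self-consistent world of patients, trials,
# criterion-level ground truth, trial-level labels and qrels, plus a
# deterministic mock backend, so the whole pipeline runs and is measurable
# offline. Notes are rendered one clinical fact per sentence, which makes
# the true evidence sentence IDs exactly checkable.

cohort_schema <- function() {
  conditions <- c("glioblastoma", "type 2 diabetes mellitus",
                  "chronic obstructive pulmonary disease",
                  "rheumatoid arthritis", "major depressive disorder",
                  "atrial fibrillation", "psoriasis",
                  "chronic kidney disease", "asthma", "breast carcinoma",
                  "Parkinson disease", "ulcerative colitis")
  meds <- list(
    "glioblastoma" = c("temozolomide", "bevacizumab"),
    "type 2 diabetes mellitus" = c("metformin", "semaglutide"),
    "chronic obstructive pulmonary disease" = c("tiotropium", "salmeterol"),
    "rheumatoid arthritis" = c("methotrexate", "adalimumab"),
    "major depressive disorder" = c("sertraline", "bupropion"),
    "atrial fibrillation" = c("apixaban", "metoprolol"),
    "psoriasis" = c("secukinumab", "calcipotriol"),
    "chronic kidney disease" = c("dapagliflozin", "lisinopril"),
    "asthma" = c("budesonide", "montelukast"),
    "breast carcinoma" = c("tamoxifen", "letrozole"),
    "Parkinson disease" = c("levodopa", "pramipexole"),
    "ulcerative colitis" = c("mesalamine", "infliximab"))
  list(
    conditions = conditions, meds = meds,
    comorbidities = c("congestive heart failure", "cirrhosis", "epilepsy",
                      "active tuberculosis", "HIV infection"),
    drugs = c("warfarin", "prednisone", "cyclosporine", "lithium"),
    fillers = c(
      "Vital signs are within normal limits.",
      "The review of systems is otherwise unremarkable.",
      "There are no known allergies.",
      "The physical examination is otherwise normal.",
      "The patient lives at home and is independent in daily activities.",
      "There is no relevant family history to report.",
      "The patient denies fever, chills, or recent weight loss.",
      "Follow-up was arranged with the primary care clinic.",
      "The patient has never smoked and drinks alcohol only occasionally.",
      "Appetite and sleep are reported as normal.",
      "The remainder of the social history is noncontributory.",
      "The patient is employed and reports a stable home situation."))
}

fmt1 <- function(x) format(round(x, 1), nsmall = 1, trim = TRUE)

simulate_patient <- function(id, schema, n_conditions, unmentioned_rate,
                             note_length_words) {
  condition <- sample(schema$conditions[seq_len(n_conditions)], 1L)
  age <- min(max(round(rnorm(1, 40, 20)), 18L), 90L)
  sex <- sample(c("male", "female"), 1L)
  meds <- sample(schema$meds[[condition]],
                 sample(1:2, 1L, prob = c(0.4, 0.6)))
  comorbidity <- if (runif(1) < 0.15) sample(schema$comorbidities, 1L) else NA
  drug <- if (runif(1) < 0.10) sample(schema$drugs, 1L) else NA
  pregnant <- if (sex == "female") runif(1) < 0.10 else FALSE
  labs <- c(hb = max(rnorm(1, 13.5, 1.8), 6),
            creat = max(rnorm(1, 1.0, 0.35), 0.4),
            hba1c = max(rnorm(1, 6.0, 1.2), 4.5),
            plt = max(rnorm(1, 250, 70), 50))
  groups <- c("meds", "comorbidity", "drug", "pregnancy",
              "hb", "creat", "hba1c", "plt")
  mentioned <- setNames(runif(length(groups)) >= unmentioned_rate, groups)

  pron <- if (sex == "female") "She" else "He"
  sentences <- character(); sid <- list()
  add <- function(s) { sentences[[length(sentences) + 1L]] <<- s
                       length(sentences) - 1L }
  sid$age <- sid$sex <- add(sprintf("The patient is a %d-year-old %s.",
                                    age, sex))
  sid$condition <- add(sprintf("The medical history is significant for %s.",
                               condition))
  sid$meds <- integer()
  if (mentioned[["meds"]]) {
    for (m in meds) sid$meds[[m]] <- add(sprintf(
      "Current medications include %s.", m))
  }
  if (sex == "female" && mentioned[["pregnancy"]]) {
    sid$pregnancy <- add(if (pregnant) "She is currently pregnant." else
      "She is not currently pregnant.")
  }
  if (!is.na(comorbidity) && mentioned[["comorbidity"]]) {
    sid$comorbidity <- add(sprintf(
      "Past medical history is also notable for %s.", comorbidity))
  }
  if (!is.na(drug) && mentioned[["drug"]]) {
    sid$drug <- add(sprintf("%s additionally takes %s.", pron, drug))
  }
  if (mentioned[["hb"]]) sid$hb <- add(sprintf(
    "Laboratory testing shows a hemoglobin of %s g/dL.", fmt1(labs[["hb"]])))
  if (mentioned[["creat"]]) sid$creat <- add(sprintf(
    "The serum creatinine is %s mg/dL.", fmt1(labs[["creat"]])))
  if (mentioned[["hba1c"]]) sid$hba1c <- add(sprintf(
    "The most recent HbA1c is %s percent.", fmt1(labs[["hba1c"]])))
  if (mentioned[["plt"]]) sid$plt <- add(sprintf(
    "The platelet count is %d.", round(labs[["plt"]])))

  target <- round(note_length_words * runif(1, 0.8, 1.2))
  n_fill <- length(schema$fillers)
  offset <- sample.int(n_fill, 1L)
  j <- 0L
  word_count <- function() sum(lengths(strsplit(sentences, "\\s+")))
  while (word_count() < target && j < 3L * n_fill) {
    add(schema$fillers[[((offset + j) %% n_fill) + 1L]])
    j <- j + 1L
  }

  list(patient_id = id, condition = condition, age = age, sex = sex,
       meds = meds, comorbidity = comorbidity, drug = drug,
       pregnant = pregnant, labs = labs, mentioned = mentioned,
       sentences = sentences, sid = sid,
       keywords = c(condition,
                    if (mentioned[["meds"]]) meds,
                    if (!is.na(comorbidity) && mentioned[["comorbidity"]]) comorbidity,
                    if (!is.na(drug) && mentioned[["drug"]]) drug))
}

simulate_trial <- function(id, schema, n_conditions, inclusion_per_trial,
                           exclusion_per_trial) {
  condition <- sample(schema$conditions[seq_len(n_conditions)], 1L)
  intervention <- sample(schema$meds[[condition]], 1L)
  n_incl <- sample(inclusion_per_trial[1]:inclusion_per_trial[2], 1L)
  n_excl <- sample(exclusion_per_trial[1]:exclusion_per_trial[2], 1L)

  tmpl <- function(kind, text, ...) c(list(kind = kind, text = text), list(...))
  age_min <- sample(c(18L, 21L, 25L, 30L), 1L)
  age_max <- sample(c(65L, 70L, 75L, 80L, 85L), 1L)
  incl <- list(
    tmpl("condition", sprintf(
      "Histologically or clinically confirmed diagnosis of %s.", condition),
      condition = condition),
    tmpl("age", sprintf("Age between %d and %d years.", age_min, age_max),
         min = age_min, max = age_max))
  extra_pool <- list(
    hb = function() { x <- sample(c(9, 10, 11), 1L)
      tmpl("hb", sprintf("Hemoglobin of at least %s g/dL.", fmt1(x)), min = x) },
    plt = function() { x <- sample(c(100L, 125L, 150L), 1L)
      tmpl("plt", sprintf("Platelet count of at least %d.", x), min = x) },
    hba1c = function() { x <- sample(c(8.5, 9.0, 9.5, 10.0), 1L)
      tmpl("hba1c", sprintf("HbA1c below %s percent.", fmt1(x)), max = x) },
    med = function() { m <- sample(schema$meds[[condition]], 1L)
      tmpl("med", sprintf("Currently receiving treatment with %s.", m),
           med = m) })
  n_extra <- max(n_incl - 2L, 0L)
  for (key in sample(names(extra_pool), min(n_extra, length(extra_pool)))) {
    incl[[length(incl) + 1L]] <- extra_pool[[key]]()
  }

  excl <- list()
  excl_pool <- list(
    pregnancy = function() tmpl("pregnancy", "Pregnant or breastfeeding women."),
    comorbidity = function() { cm <- sample(schema$comorbidities, 1L)
      tmpl("comorbidity", sprintf("History of %s.", cm), comorbidity = cm) },
    drug = function() { d <- sample(schema$drugs, 1L)
      tmpl("drug", sprintf("Current use of %s.", d), drug = d) },
    creat = function() { x <- sample(c(1.8, 2.0, 2.2), 1L)
      tmpl("creat", sprintf("Serum creatinine above %s mg/dL.", fmt1(x)),
           max = x) })
  for (key in sample(names(excl_pool), min(n_excl, length(excl_pool)))) {
    excl[[length(excl) + 1L]] <- excl_pool[[key]]()
  }

  list(trial_id = id, condition = condition, intervention = intervention,
       title = sprintf("A Randomized Study of %s in %s",
                       intervention, condition),
       brief_summary = sprintf(
         "This study evaluates %s for the treatment of %s in adults.",
         intervention, condition),
       incl_templates = incl, excl_templates = excl)
}

# True (label, evidence sentence ids) for one criterion template against one
# simulated patient; the note is treated as complete except for attribute
# groups explicitly flagged unmentioned, which yield not_enough_information.
decide_criterion <- function(template, patient, criterion_type) {
  met_label <- if (criterion_type == "inclusion") "included" else "excluded"
  unmet_label <- if (criterion_type == "inclusion") "not_included" else
    "not_excluded"
  lab_case <- function(group, value_met, evidence) {
    if (!patient$mentioned[[group]]) {
      list(label = "not_enough_information", sentence_ids = integer())
    } else if (value_met) {
      list(label = met_label, sentence_ids = as.integer(evidence))
    } else {
      list(label = unmet_label, sentence_ids = as.integer(evidence))
    }
  }
  k <- template$kind
  if (k == "condition") {
    met <- identical(patient$condition, template$condition)
    list(label = if (met) met_label else unmet_label,
         sentence_ids = patient$sid$condition)
  } else if (k == "age") {
    met <- patient$age >= template$min && patient$age <= template$max
    list(label = if (met) met_label else unmet_label,
         sentence_ids = patient$sid$age)
  } else if (k == "hb") {
    lab_case("hb", patient$labs[["hb"]] >= template$min, patient$sid$hb)
  } else if (k == "plt") {
    lab_case("plt", patient$labs[["plt"]] >= template$min, patient$sid$plt)
  } else if (k == "hba1c") {
    lab_case("hba1c", patient$labs[["hba1c"]] < template$max,
             patient$sid$hba1c)
  } else if (k == "med") {
    lab_case("meds", template$med %in% patient$meds,
             unname(patient$sid$meds))
  } else if (k == "pregnancy") {
    if (patient$sex == "male") {
      list(label = "not_applicable", sentence_ids = integer())
    } else {
      lab_case("pregnancy", isTRUE(patient$pregnant), patient$sid$pregnancy)
    }
  } else if (k == "comorbidity") {
    if (is.na(patient$comorbidity) ||
        patient$comorbidity != template$comorbidity) {
      list(label = unmet_label, sentence_ids = integer())
    } else {
      lab_case("comorbidity", TRUE, patient$sid$comorbidity)
    }
  } else if (k == "drug") {
    if (is.na(patient$drug) || patient$drug != template$drug) {
      list(label = unmet_label, sentence_ids = integer())
    } else {
      lab_case("drug", TRUE, patient$sid$drug)
    }
  } else if (k == "creat") {
    lab_case("creat", patient$labs[["creat"]] > template$max,
             patient$sid$creat)
  } else {
    abort(sprintf("Unknown criterion template kind `%s`.", k))
  }
}

# Trial-level label from criterion truths: irrelevant iff the primary
# condition mismatches; excluded iff any exclusion criterion is met or any
# inclusion criterion unmet while the condition matches; eligible iff all
# applicable inclusion criteria are met and no exclusion criterion is met;
# otherwise potential.
derive_cohort_label <- function(incl_labels, excl_labels, condition_match) {
  if (!condition_match) return("irrelevant")
  if (any(excl_labels == "excluded") || any(incl_labels == "not_included")) {
    return("excluded")
  }
  applicable <- incl_labels[incl_labels != "not_applicable"]
  if (all(applicable == "included")) "eligible" else "potential"
}

#' Generate a synthetic patient-trial cohort
#'
#' Simulates patients (primary condition, demographics, medications,
#' comorbidities, labs), trials (condition-targeted criteria built from
#' decidable templates), per-criterion ground-truth eligibility labels with
#' their true evidence sentence IDs, trial-level cohort labels, and graded
#' qrels. Notes are written one fact per sentence; each referenced attribute
#' group is omitted from the note with probability `unmentioned_rate`, which
#' induces true `not_enough_information` labels. The number of distinct
#' primary conditions is chosen as `round(1 / (1 - irrelevant_fraction))` so
#' that roughly that fraction of trials is irrelevant to each patient.
#' Everything is reproducible for a given `seed`.
#'
#' @param n_patients,n_trials Cohort sizes.
#' @param seed Integer seed controlling all randomness.
#' @param note_length_words Target mean note length in words (default 120);
#'   the achieved mean is within 15% of the target.
#' @param inclusion_per_trial,exclusion_per_trial Integer ranges
#'   `c(min, max)` of criteria per trial and type (inclusion minimum 2: a
#'   condition and an age criterion are always present).
#' @param unmentioned_rate Probability that an attribute group is left out of
#'   the note (default 0.1).
#' @param irrelevant_fraction Approximate fraction of trials irrelevant to a
#'   patient (default 0.8).
#' @return A `synthetic_cohort` list with `corpus`, `patients`, `qrels`
#'   (including `cohort_label`), `criterion_truth`, `patient_keywords`, and
#'   `params`.
#' @export
generate_cohort <- function(n_patients = 20L, n_trials = 200L, seed = 1L,
                            note_length_words = 120,
                            inclusion_per_trial = c(2L, 6L),
                            exclusion_per_trial = c(0L, 4L),
                            unmentioned_rate = 0.1,
                            irrelevant_fraction = 0.8) {
  assert_scalar_number(n_patients, "n_patients", min = 1)
  assert_scalar_number(n_trials, "n_trials", min = 1)
  assert_scalar_number(note_length_words, "note_length_words", min = 20)
  if (!is.numeric(unmentioned_rate) || unmentioned_rate < 0 ||
      unmentioned_rate > 1) {
    abort("`unmentioned_rate` must be in [0, 1].",
          class = "trialmatchr_config_error")
  }
  if (irrelevant_fraction < 0 || irrelevant_fraction > 0.95) {
    abort("`irrelevant_fraction` must be in [0, 0.95].",
          class = "trialmatchr_config_error")
  }
  if (inclusion_per_trial[1] < 2 || inclusion_per_trial[2] > 20 ||
      exclusion_per_trial[1] < 0 || exclusion_per_trial[2] > 20) {
    abort("Criteria-per-trial ranges must lie in [2, 20] (inclusion) and [0, 20] (exclusion).",
          class = "trialmatchr_config_error")
  }
  schema <- cohort_schema()
  n_conditions <- min(max(2L, round(1 / (1 - irrelevant_fraction))),
                      length(schema$conditions))

  withr::with_seed(as.integer(seed), {
    sim_patients <- lapply(seq_len(n_patients), function(i) {
      simulate_patient(sprintf("synthetic-patient-%03d", i), schema,
                       n_conditions, unmentioned_rate, note_length_words)
    })
    sim_trials <- lapply(seq_len(n_trials), function(i) {
      simulate_trial(sprintf("NCT%08d", i), schema, n_conditions,
                     inclusion_per_trial, exclusion_per_trial)
    })
  })

  corpus <- as_trial_corpus(tibble(
    trial_id = map_chr(sim_trials, "trial_id"),
    title = map_chr(sim_trials, "title"),
    conditions = map(sim_trials, ~ .x$condition),
    interventions = map(sim_trials, ~ .x$intervention),
    brief_summary = map_chr(sim_trials, "brief_summary"),
    inclusion_criteria = map(sim_trials,
                             ~ map_chr(.x$incl_templates, "text")),
    exclusion_criteria = map(sim_trials,
                             ~ map_chr(.x$excl_templates, "text"))))
  patients <- as_patient_notes(tibble(
    patient_id = map_chr(sim_patients, "patient_id"),
    text = map_chr(sim_patients, ~ paste(.x$sentences, collapse = " "))))

  truth_rows <- vector("list", n_patients * n_trials)
  pair_rows <- vector("list", n_patients * n_trials)
  k <- 0L
  for (p in sim_patients) {
    for (t in sim_trials) {
      k <- k + 1L
      one_side <- function(templates, type) {
        lapply(seq_along(templates), function(ci) {
          d <- decide_criterion(templates[[ci]], p, type)
          tibble(patient_id = p$patient_id, trial_id = t$trial_id,
                 criterion_type = type, criterion_index = ci - 1L,
                 label = d$label, sentence_ids = list(sort(d$sentence_ids)))
        })
      }
      crit <- bind_rows(c(one_side(t$incl_templates, "inclusion"),
                          one_side(t$excl_templates, "exclusion")))
      truth_rows[[k]] <- crit
      lab <- derive_cohort_label(
        crit$label[crit$criterion_type == "inclusion"],
        crit$label[crit$criterion_type == "exclusion"],
        identical(p$condition, t$condition))
      pair_rows[[k]] <- tibble(patient_id = p$patient_id,
                               trial_id = t$trial_id, cohort_label = lab)
    }
  }
  qrels <- bind_rows(pair_rows)
  qrels$grade <- relevance_of(qrels$cohort_label)

  structure(list(
    corpus = corpus, patients = patients,
    qrels = qrels[, c("patient_id", "trial_id", "grade", "cohort_label")],
    criterion_truth = bind_rows(truth_rows),
    patient_keywords = tibble(
      patient_id = map_chr(sim_patients, "patient_id"),
      keywords = map(sim_patients, "keywords")),
    params = list(n_patients = n_patients, n_trials = n_trials, seed = seed,
                  note_length_words = note_length_words,
                  inclusion_per_trial = inclusion_per_trial,
                  exclusion_per_trial = exclusion_per_trial,
                  unmentioned_rate = unmentioned_rate,
                  irrelevant_fraction = irrelevant_fraction,
                  n_conditions = n_conditions)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients x %d trials, seed %s>\n",
              nrow(x$patients), nrow(x$corpus), x$params$seed))
  print(table(x$qrels$cohort_label))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `corpus.jsonl`, `patients.jsonl`, `qrels.txt` (TREC format),
#' `ground_truth.jsonl` (per-pair cohort label plus criterion-level truth)
#' and `keywords.jsonl` (each patient's attribute terms in salience order,
#' used by the oracle backend) into `dir`. [read_cohort()] restores the
#' cohort from such a directory.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_corpus(cohort$corpus, file.path(dir, "corpus.jsonl"))
  write_patient_notes(cohort$patients, file.path(dir, "patients.jsonl"))
  write_qrels(cohort$qrels, file.path(dir, "qrels.txt"))
  ct <- cohort$criterion_truth
  key <- paste(ct$patient_id, ct$trial_id, sep = "\r")
  labels <- setNames(cohort$qrels$cohort_label,
                     paste(cohort$qrels$patient_id, cohort$qrels$trial_id,
                           sep = "\r"))
  recs <- lapply(split(seq_len(nrow(ct)), factor(key, levels = unique(key))),
                 function(idx) {
    sub <- ct[idx, ]
    list(patient_id = sub$patient_id[[1]], trial_id = sub$trial_id[[1]],
         cohort_label = unname(labels[[paste(sub$patient_id[[1]],
                                             sub$trial_id[[1]], sep = "\r")]]),
         criteria = lapply(seq_len(nrow(sub)), function(i) {
           list(criterion_type = sub$criterion_type[[i]],
                criterion_index = sub$criterion_index[[i]],
                label = sub$label[[i]],
                sentence_ids = as.list(sub$sentence_ids[[i]]))
         }))
  })
  write_jsonl(unname(recs), file.path(dir, "ground_truth.jsonl"))
  write_jsonl(lapply(seq_len(nrow(cohort$patient_keywords)), function(i) {
    list(patient_id = cohort$patient_keywords$patient_id[[i]],
         keywords = as.list(cohort$patient_keywords$keywords[[i]]))
  }), file.path(dir, "keywords.jsonl"))
  invisible(dir)
}

#' Read a synthetic cohort back from disk
#'
#' Restores a cohort written by [write_cohort()] so that [mock_backend()] can
#' be rebuilt from files, e.g. for command-line runs.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `synthetic_cohort` list.
#' @export
read_cohort <- function(dir) {
  gt <- read_jsonl(file.path(dir, "ground_truth.jsonl"))
  crit <- bind_rows(lapply(gt, function(r) {
    n <- length(r$criteria)
    tibble::new_tibble(list(
      patient_id = rep(r$patient_id, n), trial_id = rep(r$trial_id, n),
      criterion_type = map_chr(r$criteria, "criterion_type"),
      criterion_index = map_int(r$criteria,
                                ~ as.integer(.x$criterion_index)),
      label = map_chr(r$criteria, "label"),
      sentence_ids = map(r$criteria,
                         ~ as.integer(unlist(.x$sentence_ids)))), nrow = n)
  }))
  labels <- tibble(patient_id = map_chr(gt, "patient_id"),
                   trial_id = map_chr(gt, "trial_id"),
                   cohort_label = map_chr(gt, "cohort_label"))
  qrels <- read_qrels(file.path(dir, "qrels.txt")) |>
    left_join(labels, by = c("patient_id", "trial_id"))
  kw <- read_jsonl(file.path(dir, "keywords.jsonl"))
  structure(list(
    corpus = read_trial_corpus(file.path(dir, "corpus.jsonl")),
    patients = read_patient_notes(file.path(dir, "patients.jsonl")),
    qrels = qrels, criterion_truth = crit,
    patient_keywords = tibble(
      patient_id = map_chr(kw, "patient_id"),
      keywords = map(kw, ~ as.character(unlist(.x$keywords)))),
    params = list(n_patients = NA, n_trials = NA, seed = NA)
  ), class = "synthetic_cohort")
}

flip_label <- function(label, criterion_type, u) {
  others <- setdiff(eligibility_labels(criterion_type), label)
  others[floor(u * length(others)) + 1L]
}

#' Deterministic mock language-model backend
#'
#' Answers backend requests from the cohort's ground truth, standing in for a
#' live model: keyword requests return the patient's attribute terms in
#' salience order (condition first); matching requests return well-formed
#' structured output with the true labels and evidence sentence IDs, each
#' label independently flipped to a random wrong label of the same set with
#' probability `noise`; aggregation requests return relevance/eligibility
#' scores derived from the true trial-level label — the relevance is
#' `100 * grade / 2` (eligible 100, potential and excluded 50, irrelevant 0)
#' and the eligibility is a consistent signed score (+100, +25, -50, 0
#' respectively, always within `[-R, R]`). Flip decisions
#' are derived from per-(pair, criterion) hashes of `seed`, so outputs are
#' reproducible and flip sets are nested across noise levels. Querying a pair
#' absent from the ground truth is an error.
#'
#' The `mode` argument selects deliberately faulty behaviours for robustness
#' testing: `"corrupted"` emits truncated, unparseable matching output;
#' `"wrong_label"` emits inclusion-set labels on exclusion calls;
#' `"out_of_range"` emits sentence IDs beyond the note length.
#'
#' @param cohort A [generate_cohort()] result.
#' @param noise Per-criterion label flip probability in `[0, 1]`.
#' @param seed Integer seed for the flip hashes.
#' @param mode `"oracle"` (default) or one of the faulty modes above.
#' @return An [llm_backend()].
#' @export
mock_backend <- function(cohort, noise = 0, seed = 1L,
                         mode = c("oracle", "corrupted", "wrong_label",
                                  "out_of_range")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mode <- match.arg(mode)
  if (!is.numeric(noise) || noise < 0 || noise > 1) {
    abort("`noise` must be in [0, 1].", class = "trialmatchr_config_error")
  }
  truth <- cohort$criterion_truth
  truth_key <- paste(truth$patient_id, truth$trial_id, truth$criterion_type,
                     sep = "\r")
  truth_env <- list2env(split(seq_len(nrow(truth)), truth_key),
                        hash = TRUE, parent = emptyenv())
  keywords <- setNames(cohort$patient_keywords$keywords,
                       cohort$patient_keywords$patient_id)
  pair_env <- list2env(
    as.list(setNames(cohort$qrels$cohort_label,
                     paste(cohort$qrels$patient_id, cohort$qrels$trial_id,
                           sep = "\r"))),
    hash = TRUE, parent = emptyenv())

  handler <- function(request) {
    if (request$type == "keywords") {
      kw <- keywords[[request$patient_id]]
      if (is.null(kw)) {
        abort(sprintf("Mock backend has no ground truth for patient %s.",
                      request$patient_id),
              class = "trialmatchr_backend_error")
      }
      return(as.character(jsonlite::toJSON(kw)))
    }
    if (request$type == "matching") {
      idx <- get0(paste(request$patient_id, request$trial_id,
                        request$criterion_type, sep = "\r"),
                  envir = truth_env, ifnotfound = integer())
      if (length(idx) == 0L) {
        abort(sprintf("Mock backend has no ground truth for pair (%s, %s).",
                      request$patient_id, request$trial_id),
              class = "trialmatchr_backend_error")
      }
      sub <- truth[idx, ]
      sub <- sub[order(sub$criterion_index), ]
      out <- list()
      for (i in seq_len(nrow(sub))) {
        lab <- sub$label[[i]]
        ids <- sub$sentence_ids[[i]]
        if (noise > 0) {
          key <- paste(request$patient_id, request$trial_id,
                       request$criterion_type, sub$criterion_index[[i]],
                       sep = "\r")
          u <- hashed_runif(paste0("flip\r", key), seed)
          if (u < noise) {
            lab <- flip_label(lab, request$criterion_type,
                              hashed_runif(paste0("pick\r", key), seed))
          }
        }
        if (mode == "wrong_label" && request$criterion_type == "exclusion") {
          lab <- "included"
        }
        if (mode == "out_of_range") {
          ids <- c(ids, request$n_sentences + 3L)
        }
        out[[as.character(sub$criterion_index[[i]])]] <- list(
          explanation = sprintf(
            "The note sentences %s determine that the criterion is %s.",
            if (length(ids) == 0) "(none)" else paste(ids, collapse = ", "),
            gsub("_", " ", lab)),
          sentence_ids = as.list(ids),
          label = gsub("_", " ", lab))
      }
      txt <- as.character(jsonlite::toJSON(out, auto_unbox = TRUE))
      if (mode == "corrupted") {
        txt <- substr(txt, 1, max(nchar(txt) %/% 3, 10))
      }
      return(txt)
    }
    if (request$type == "aggregation") {
      lab <- get0(paste(request$patient_id, request$trial_id, sep = "\r"),
                  envir = pair_env, ifnotfound = NULL)
      if (is.null(lab)) {
        abort(sprintf("Mock backend has no ground truth for pair (%s, %s).",
                      request$patient_id, request$trial_id),
              class = "trialmatchr_backend_error")
      }
      # R encodes the graded relevance of the true trial-level label
      # (100 * grade / 2); S is a consistent eligibility score with |S| <= R.
      rs <- switch(lab,
        eligible = c(100, 100), potential = c(50, 25),
        excluded = c(50, -50), irrelevant = c(0, 0),
        unlabeled = c(0, 0))
      return(as.character(jsonlite::toJSON(
        list(relevance = rs[[1]], eligibility = rs[[2]]), auto_unbox = TRUE)))
    }
    abort(sprintf("Mock backend cannot handle request type `%s`.",
                  request$type), class = "trialmatchr_backend_error")
  }
  llm_backend(handler, model_id = sprintf("mock-%s-noise%g", mode, noise),
              temperature = 0)
}
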