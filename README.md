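# trialmatchr

Ranking clinical trials for a patient from a free-text clinical note.

Recruiting patients into clinical trials requires checking a note against
the inclusion and exclusion criteria of every candidate trial — thousands of
criteria across tens of thousands of registered trials. `trialmatchr`
implements a three-stage architecture for this task, for clinical
informaticians and medical-NLP researchers who want the full pipeline —
retrieval, criterion-level matching with a language model, trial-level
ranking, and graded evaluation — as testable, deterministic R code with the
language model behind a pluggable interface.

## The model

**Retrieval.** A backend generates up to 32 search keywords
`w_1, ..., w_K`, ranked by importance. Each keyword queries a lexical
retriever (Okapi BM25, `k1 = 1.5`, `b = 0.75`) and a semantic retriever (a
pluggable text embedder ranked by inner product). The per-keyword rankings
are fused by weighted reciprocal ranks:

    s_j = sum over retrievers, sum over i = 1..K of
          1 / ( i * ( Rank(Ret, w_i, t_j) + C ) ),    C = 20

and the top 500 trials by `s_j` become the candidates.

**Matching.** For each candidate pair, two backend calls — one for all
inclusion criteria, one for all exclusion criteria — return, per criterion,
a free-text explanation `R`, the 0-based IDs `S` of the note sentences
supporting it, and an eligibility label `E` from
`{included, not included, not enough information, not applicable}`
(inclusion) or `{excluded, not excluded, not enough information,
not applicable}` (exclusion). Output is strictly validated; failed pairs are
recorded and never silently imputed.

**Ranking.** With `M'` applicable inclusion criteria (`M` minus
`not applicable`), the label counts over `M'` give `%met`, `%unmet` and
`%no-info` (likewise `N'` for exclusion). The backend also aggregates the
criterion results into a relevance `R ∈ [0, 100]` and an eligibility
`S ∈ [−R, R]`, and the combined score is

    combined = %met_incl − I(%unmet_incl > 0) − I(%met_excl > 0)
               + R/100 + S/100 .

Any single feature or the combination, with task-appropriate signs, ranks
candidates (higher = more suitable) or flags explicitly ineligible trials
(higher = more likely excluded). Evaluation uses graded relevance
(eligible = 2, excluded/potential = 1, irrelevant = 0): graded Recall@k,
NDCG@10, graded P@10, and the tie-corrected Mann–Whitney AUROC.

A synthetic cohort generator (`generate_cohort()`) plus a deterministic
oracle backend (`mock_backend()`) provide a closed world with known
criterion-level ground truth, so everything runs and is measurable without
network access; adapters for NLI-style predictors (`map_nli_labels()`,
`baseline_combination()`) make external criterion classifiers comparable.

## Worked example

```r
library(trialmatchr)

cohort  <- generate_cohort(n_patients = 3, n_trials = 30, seed = 2)
backend <- mock_backend(cohort, noise = 0, seed = 2)
cohort
#> <synthetic_cohort: 3 patients x 30 trials, seed 2>
#>   eligible   excluded irrelevant
#>         11          3         76

res <- run_pipeline(cohort$patients, cohort$corpus, backend,
                    out_dir = "demo_out",
                    config = run_config(top_k = 30, feature = "relevance"),
                    qrels = cohort$qrels)

res$ranking[1:5, ]
#> # A tibble: 5 × 5
#>   patient_id            trial_id     rank score tag
#>   <chr>                 <chr>       <int> <dbl> <chr>
#> 1 synthetic-patient-001 NCT00000004     1     1 trialmatchr
#> 2 synthetic-patient-001 NCT00000008     2     1 trialmatchr
#> 3 synthetic-patient-001 NCT00000015     3     1 trialmatchr
#> 4 synthetic-patient-001 NCT00000017     4     1 trialmatchr
#> 5 synthetic-patient-001 NCT00000024     5     1 trialmatchr

glance(evaluate_run(res$ranking, cohort$qrels, metrics = c("ndcg@10", "p@10")))
#> # A tibble: 1 × 2
#>   `ndcg@10` `p@10`
#>       <dbl>  <dbl>
#> 1         1  0.417

criterion_accuracy(res$matches$results, cohort$criterion_truth)
#> # A tibble: 1 × 2
#>   accuracy     n
#>      <dbl> <int>
#> 1        1   549
```

The top-ranked trials (score 1 = maximal relevance) are the patient's truly
eligible trials, so NDCG@10 is 1; P@10 is 0.417 because this patient has
fewer than ten relevant trials in a 30-trial corpus, which caps the graded
precision. With the clean oracle backend all 549 criterion-level labels
match the ground truth; raising `noise` degrades that accuracy by the flip
rate. Each stage's artifacts (`retrieval_run.txt`, `matches.jsonl`,
`scores.jsonl`, ranked runs in TREC format, `report.json`) are written to
`out_dir` with a provenance fingerprint, and backend responses are cached
so re-runs are byte-identical with zero duplicate calls.

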