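---
title: "Ranking clinical trials for a patient: models, scores, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking clinical trials for a patient: models, scores, and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmatchr)
```

## The problem

Matching a patient to recruiting clinical trials means reading a free-text
clinical note and deciding, for each candidate trial, whether the patient
satisfies its inclusion criteria and avoids its exclusion criteria. Done
manually this is slow and does not scale to registries with tens of
thousands of active trials. `trialmatchr` implements a three-stage
architecture in which a language model does the reading and a small amount
of arithmetic does the ranking:

1. **Retrieval** — generate importance-ranked search keywords from the note
   and use them to filter a large trial collection down to a few hundred
   candidates.
2. **Matching** — for each candidate trial, classify the patient against
   every criterion, producing an explanation, the supporting sentence IDs,
   and an eligibility label per criterion.
3. **Ranking** — aggregate the criterion-level labels into trial-level
   scores used to rank candidates (best trials first) or to flag explicitly
   ineligible ones.

The language model sits behind a narrow backend interface
(`llm_backend()`): a function from a request (type + rendered prompt +
structured context) to raw response text, with temperature fixed at 0 so
outputs are deterministic. Everything else — prompt construction, response
parsing, validation, aggregation, evaluation — is ordinary, testable code.
A deterministic mock backend (`mock_backend()`) answers the same requests
from simulated ground truth, so the entire pipeline runs and is measurable
offline.

## Stage 1: retrieval

`generate_keywords()` asks the backend for up to `max_keywords = 32`
keywords, ordered from most to least important; the 1-based position `i` of
a keyword is its importance rank. Each keyword is issued to two retrievers:

* **Lexical**: an Okapi BM25 index (`bm25_index()`, `bm25_rank()`) over the
  concatenated trial text (title, conditions, interventions, summary, all
  criteria), tokenized on non-alphanumeric characters. Parameters are the
  common defaults `k1 = 1.5`, `b = 0.75`; the inverse document frequency is
  the smoothed non-negative form `log(1 + (N - df + 0.5)/(df + 0.5))`, so
  "positive score" coincides with "contains at least one query term".
* **Semantic**: inner-product ranking against precomputed document
  embeddings (`semantic_index()`, `semantic_rank()`). The embedder is a
  plain function `character -> matrix`, so a dense biomedical encoder can be
  plugged in; the package ships `hash_embedder()`, a deterministic signed
  token-hashing embedder, which is what the offline tests use.

Per-keyword rankings are fused by weighted reciprocal ranks
(`fuse_rankings()`):

$$s_j = \sum_{\mathrm{Ret}} \sum_{i=1}^{K} \frac{1}{i \cdot (\mathrm{Rank}(\mathrm{Ret}, w_i, t_j) + C)}, \qquad C = 20,$$

with a `1/i` decay over keyword importance. A trial absent from one
keyword's ranking contributes 0 for that term — the limit of the formula as
the rank grows — which keeps the computation bounded; rankings are
truncated at depth 1000 before fusion, where the largest discarded
contribution is below `1/1020`. `retrieve_candidates()` keeps the `top_k =
500` trials by fused score and supports `lexical`-only and `semantic`-only
modes for ablations. Ties anywhere are broken by `trial_id` so rankings are
reproducible.

## Stage 2: criterion-level matching

A patient note is an ordered list of sentences with 0-based IDs
(`split_sentences()`); a trial contributes background text plus ordered
inclusion and exclusion criteria, also indexed from 0. For each
(patient, trial) pair, `match_trial()` makes **two** backend calls — one
covering all inclusion criteria, one covering all exclusion criteria (a
call is skipped if the list is empty). The prompt shows the numbered
criteria, the numbered note sentences, and the label set, and asks for the
explanation *before* the sentence IDs and label, so the classification is
grounded in stated reasoning.

Inclusion criteria use the label set `included / not_included /
not_enough_information / not_applicable`; exclusion criteria use `excluded
/ not_excluded / not_enough_information / not_applicable`. Exclusion
criteria get their own set because their phrasing is often elliptical
("Pregnancy.") and plain entailment labels do not carry the intended
direction.

`parse_matching_output()` validates strictly: a label from the wrong set is
a typed validation error naming the criterion index; out-of-range sentence
IDs are dropped with a warning; a criterion missing from the response is
filled with a *flagged* sentinel (`not_enough_information`, no evidence)
rather than silently imputed. A response that does not parse at all fails
the pair — `match_candidates()` records the error and continues the batch,
and failed pairs are listed in `failed_pairs.jsonl` for resumption. Raw
responses are retained verbatim for audit. Criteria are expected pre-split
in the corpus file (one criterion per array element); splitting free-text
criteria blocks is upstream of this package.

## Stage 3: trial-level scores

With `M` inclusion criteria and `M' = M - \#\mathrm{not\_applicable}`
applicable ones, `linear_aggregate()` computes `%met`, `%unmet` and
`%no-information` as label counts over `M'` (likewise `N'` for exclusion).
When `M' = 0` all three percentages are defined as 0 and a degenerate flag
is set. `llm_aggregate()` asks the backend for two aggregate scores —
general relevance `R` in `[0, 100]` and eligibility `S` — and enforces the
constraints `0 <= R <= 100` and `-R <= S <= R` (an eligibility judgment
cannot be more confident than the relevance that supports it) by clamping,
reporting every clamp. `combine_features()` merges both:

$$\mathrm{combined} = \%\mathrm{met\,incl} - \mathbb{I}(\%\mathrm{unmet\,incl} > 0) - \mathbb{I}(\%\mathrm{met\,excl} > 0) + R/100 + S/100.$$

The LLM scores are divided by a normalization constant (default 100) so all
five terms live on comparable unit scales; without it the 0–100 terms would
dominate the percentages and the "combination" would reduce to the LLM
scores alone. The constant is an explicit argument for users who want the
raw-scale behaviour.

`task_score()` assigns task-appropriate signs: for ranking,
`+%met_incl, -%unmet_incl, -%met_excl, +%unmet_excl, +R, +S` and `combined`
as-is; for excluding (higher = more likely explicitly ineligible) all signs
flip. `rank_trials()` orders each patient's candidates by the chosen
feature, ties again by `trial_id`, and refuses non-finite scores by naming
the offending pair.

Two adapters make external NLI-style criterion predictors comparable:
`map_nli_labels()` maps `entailment / contradiction / neutral` into the
eligibility label spaces, and `baseline_combination()` implements the
percentage-only combination scores
(`%met_incl - %unmet_incl - %met_excl + %unmet_excl` for ranking;
`I(%unmet_incl>0) + I(%met_excl>0) - %met_incl` for excluding).

### Which feature for which task?

The pipeline default for ranking is `combined`. For the excluding run the
default is the LLM `eligibility` score, not the negated combination, and
the reason is structural: for an explicitly excluded pair an ideal
aggregator reports high relevance and strongly negative eligibility, so
`R/100 + S/100` collapses toward 0 — exactly the value it takes for an
irrelevant pair — while the remaining linear terms of the two classes span
the same range. The negated combination therefore cannot reliably place
excluded pairs above irrelevant ones, whereas the eligibility score
separates the excluded class directly. Both choices are configurable
(`run_config(excluding_feature = ...)`).

For the same reason there is no oracle under which the combined score
reproduces a graded-relevance-perfect ranking on every patient: when fewer
than `k` trials are eligible-or-potential, grade-1 excluded pairs must
outrank grade-0 irrelevant ones, and the combined score cannot guarantee
that ordering. An aggregator that encodes graded relevance in `R` makes the
`relevance` feature the provably ideal ranking signal — this is the
configuration the end-to-end oracle checks use.

## Evaluation

Judgments are graded: 0 for irrelevant (and, under pooled judgment, for
unjudged pairs), 1 for explicitly excluded or potentially eligible, 2 for
eligible.

* `recall_at_k()` — graded recall: top-`k` relevance mass over the
  patient's total relevance mass; unjudged retrieved pairs count as 0.
  Undefined (NA) for patients with no relevant trials.
* `ndcg_at_k()` — unlabeled pairs are removed first;
  `DCG@k = sum r_x / log2(x + 1)` with the discount driven by the
  summation index (the standard definition), normalized by the ideal DCG
  over *all* of the patient's labeled trials, matching the usual
  trec-style convention.
* `precision_at_k()` — graded: top-`k` grade sum over `2k`.
* `auroc()` — the tie-corrected Mann–Whitney statistic computed from
  mid-ranks, hence invariant under monotone transforms and exactly 0.5 for
  constant scores; undefined with a single class. The test suite
  cross-checks it against an independent ROC implementation.

`evaluate_run()` macro-averages the per-patient metrics (unweighted mean
across patients) and computes AUROC once over all labeled pairs pooled
across patients, with the explicitly ineligible label as the positive
class. The report object has `tidy()`, `glance()` and `autoplot()`
methods; `recall_curve()` plots graded recall across depths.

## The synthetic cohort

`generate_cohort()` builds a closed world in which every quantity the
pipeline estimates has a known true value:

* **Patients** have a primary condition, age (normal, mean 40, sd 20,
  clipped to 18–90), sex (1:1), one or two condition-typical medications,
  occasional comorbidities and co-medications, pregnancy status, and four
  labs drawn from plausible distributions. Notes are written **one fact per
  sentence** and padded with neutral filler sentences to a target mean
  length of 120 words (between the shorter and longer note styles of
  public patient-trial collections); the achieved mean stays within 15% of
  the target. Because each fact owns a sentence, the true evidence sentence
  IDs for every criterion are known exactly, which turns evidence
  precision/recall into a checkable property rather than a judgment call.
* **Trials** target a condition and an intervention and carry 2–6 inclusion
  criteria (a condition criterion and an age range always; optionally labs
  or a required medication) and 0–4 exclusion criteria (pregnancy,
  comorbidity, co-medication, or a lab threshold), each built from a
  decidable template.
* **Ground truth**: each criterion is decided against the patient's
  attribute vector; an attribute group omitted from the note (probability
  `unmentioned_rate = 0.1`) yields `not_enough_information` with no
  evidence. The trial-level label is derived by a fixed rule — irrelevant
  iff the primary condition mismatches; excluded iff any exclusion
  criterion is met or any inclusion criterion unmet while the condition
  matches; eligible iff all applicable inclusion criteria are met and no
  exclusion criterion is met; otherwise potential. One consequence worth
  knowing: an exclusion criterion whose truth is "no information" does not
  block eligibility under this rule. Graded qrels follow from the labels.
* The number of distinct conditions is `round(1 / (1 -
  irrelevant_fraction))` (default 5), so that with uniform assignment
  roughly `irrelevant_fraction = 0.8` of trials are irrelevant to each
  patient, mirroring the sparsity of judged collections.

`mock_backend()` answers keyword requests with the patient's attribute
terms in salience order (condition first, then medications, comorbidity,
co-medication), matching requests with well-formed JSON built from the
criterion truths, and aggregation requests with `R = 100 * grade / 2` and a
consistent signed eligibility (`+100 / +25 / -50 / 0` for eligible /
potential / excluded / irrelevant). A per-criterion flip probability
(`noise`) corrupts labels to a random wrong label of the same set; flip
decisions are uniforms hashed from the (pair, criterion) identity and the
seed, so flip sets are *nested* across noise levels — the comparison across
a noise grid is a coupled, common-random-numbers experiment. Faulty modes
(`corrupted`, `wrong_label`, `out_of_range`) exercise the parser's error
paths.

What passing tests on this world do **not** show: real clinical notes are
not one-fact-per-sentence, real criteria are not drawn from decidable
templates, real annotators disagree with mechanical label derivation, and a
live language model is not an oracle. The simulator validates the
*plumbing and arithmetic* — retrieval fusion, parsing, aggregation,
metrics, determinism — not clinical performance; measured values on this
cohort (e.g. perfect recall or accuracy with the clean oracle) are
properties of the construction, not claims about real data.

## Numerical and design choices

* All randomness flows from explicit integer seeds; cohort generation is
  wrapped in a seed context and mock-backend draws are hashed per item, so
  equal seeds give byte-identical artifacts.
* Ties are always broken by `trial_id`; runs, matches and scores are
  written with deterministic formatting, so re-running an unchanged
  configuration changes no output bytes (the test suite asserts this).
* Backend responses are cached on disk keyed by a content hash of
  (model id, temperature, request type, prompt); reruns over completed
  pairs make zero duplicate backend calls.
* Degenerate inputs: zero applicable criteria give zero percentages plus a
  flag; empty criterion lists skip the backend call; empty keyword output
  is an error carrying the raw response; single-class AUROC and
  zero-relevance recall are reported as NA rather than invented numbers.
* Test problem sizes: unit tests run on a 6-patient x 60-trial cohort; the
  end-to-end and noise-grid checks use 20 patients x 200 trials with seed
  1 and noise levels {0, 0.1, 0.2, 0.4} — large enough that ~24,000
  criterion decisions pin the flip-rate estimate, small enough to run
  comfortably on one CPU.

## Limitations

The keyword-generation and matching prompts implement the documented
contracts but are this package's own templates, not a replication of any
specific production prompt. Criteria segmentation, recruitment-status and
geographic filtering, and EHR ingestion are out of scope. The neural
retriever is represented by its interface; no encoder is trained or
shipped. Statistical comparison between systems (significance testing) is
not provided.
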