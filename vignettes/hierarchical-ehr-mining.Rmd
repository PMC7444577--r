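---
title: "Mining hierarchical EHR representations for case-control prediction"
author: "ehrmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining hierarchical EHR representations for case-control prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrmine)
```

## The problem

Hospital electronic health records (EHRs) document symptoms, findings,
diagnoses, drugs, procedures and lab tests over years of care.  Used as
input to a classifier, they could in principle flag patients on a
trajectory toward a serious diagnosis — cervical cancer is the motivating
example throughout this package — before the diagnosis is made.  Three
properties make this hard: the feature space is enormous (tens of
thousands of distinct clinical expressions), the signal is diluted by
spelling variation and by hierarchically redundant codings, and the
design is heavily imbalanced (each case is age-matched to ten controls).

`ehrmine` implements the full representation-mining pipeline for this
setting: a seeded synthetic-cohort generator standing in for protected
hospital data, cohort selection and time censoring, constrained
edit-distance normalization of free-text clinical entities, a
word-containment hierarchy over text events together with ICD-10/ATC
code rollups, sparse feature matrices under four encodings, filter-based
feature ranking, and a cross-validated classifier harness evaluated
across a grid of prediction horizons.

## The synthetic cohort generator

Real hospital EHRs cannot be redistributed, so the package's study
conditions are defined by `ehr_config()` / `generate_cohort()`.  The
generator is first-class, tested code: every recovery experiment in the
package is an experiment against its ground truth.

What it emulates, and the defaults it fixes:

* **Matched case-control design.** `n_cases` cases (default 100), each
  age-matched (uniform 25–70) to `control_ratio` (default 10) controls
  that copy the case's age.  Age is never a feature; matching removes it
  as a confounder by construction.
* **Volume asymmetry.** Cases average 187 recorded events strictly
  before diagnosis; controls average 282 in total.  The asymmetry is
  produced the way it arises in a real extraction: case streams stop at
  diagnosis while control streams continue past the matched case's index
  date.  The control window is sized so both groups share one underlying
  daily event rate (`history_days` = 730 before the index plus a derived
  follow-on window).
* **Overdispersed documentation intensity.** Per-patient event totals
  are Poisson mixed over a gamma multiplier (shape 2, mean 1).  Real
  per-patient volumes vary far more than Poisson; this choice also has a
  methodological consequence discussed under *Feature ranking* below.
* **A heavy-tailed text vocabulary with containment structure.**
  Background text entities are compounds of 1–4 pseudo-words drawn from
  a Zipf-weighted word list (exponents 0.8 for words, 0.7 for surfaces,
  6000 surfaces by default), so short general expressions are common,
  long specific ones rare, and the word-containment hierarchy has the
  top-heavy shape observed in clinical corpora.  The 6000-surface
  default scales the real-world ratio of vocabulary to cohort size down
  to the default 1100 patients.
* **Planted discriminative events.** Twenty events (text entities,
  diagnosis codes, procedure codes) with case/control prevalence
  contrasts of the magnitude seen in published top-feature tables for
  cervical cancer (case prevalence 5–44%, control prevalence under 4%).
  Their timing in cases decays exponentially before diagnosis
  (`signal_decay_days`, default 90), encoding the observation that
  predictive signal concentrates close to the diagnosis.
* **Noise channels.** Distance-1 spelling corruptions of text surfaces
  (`variant_rate`, default 0.15, preserving every word's first letter),
  negation flags (10% of findings, 6% of disorders), family-history note
  sections, patient-unique singleton events, and lab values drawn around
  fixed reference ranges.

What it does **not** emulate: free-running clinical narrative (entities
arrive pre-extracted, as if from an upstream NER system), co-morbidity
correlation structure between events, drift of coding practice over
calendar time, and per-unit lab heterogeneity.  A green test suite
therefore demonstrates that the pipeline recovers structure *of the kind
planted*, not that it would perform identically on real records.

## Cohort construction and censoring

`select_cohort()` applies the inclusion rules of the design: carriers of
the exclusion code (default `Z854C`, previous disease) are removed;
cases must have at least one event strictly before their diagnosis date
(otherwise there is nothing to predict from); undated cases are dated by
their first qualifying diagnosis code; controls carrying the
case-defining code prefix (default `C53`) are removed.

`censor_events()` implements prediction horizons: at cutoff $c$, a case
keeps exactly the events at least $c$ days before diagnosis ("at least"
read inclusively), while control streams are never truncated.  The
default grid `default_censor_grid()` is 1 day, then 14 days and every 30
days up to a year (`1, 14, 44, …, 344, 365`); the grid is configurable
because reasonable variants (e.g. multiples of 30 after the 14-day
point) exist and the choice is not scientifically forced.

Rare events — surfaces occurring for a single patient, however many
times — cannot help discrimination and only add dimensions;
`remove_rare_events()` drops them before the development/test split, so
patient-level support is counted on the whole cohort.

## Spelling normalization by constrained edit distance

Clinical text spells one concept many ways, mostly by in-word
misspellings, inflections, or compound-versus-spaced writing.
`build_groups()` groups the lemmatized vocabulary by a constrained
Levenshtein rule (`linkable()`):

* equal word count ≥ 2: every aligned word pair within distance 1, at
  most one pair at exactly 1, all first letters equal;
* single words: whole-string distance ≤ 1 and same first letter;
* differing word counts: whole-string distance ≤ 1 and same first
  letter (this clause is what lets `"thyroidea cancer"` join
  `"thyroideacancer"` — a per-word rule cannot link them).

Groups are the *connected components* of the linkable graph (chain
linkage: membership requires distance 1 to *some* member, not to all),
and every member is rewritten to the group's most frequent surface, ties
broken to the lexicographically smallest for determinism.  Chain linkage
can in principle bridge unrelated terms through intermediate spellings;
with first-letter anchoring and distance 1 this is rare, and the package
implements the rule literally rather than adding ad-hoc guards.
Candidate edges are pre-filtered to pairs sharing a first letter and
within one character in total length — both necessary conditions — so
the filter is exact, not approximate.

The negation marker `NEG::` (attached by `apply_text_policies()` under
the `separate` policy) is transparent to normalization: marked and
unmarked mentions share a spelling group, and the marker is re-attached
after rewriting.

## The event hierarchy

`build_text_hierarchy()` organizes canonical text surfaces by word-set
containment: `p` is an ancestor of `c` when `p`'s word set is a strict
subset of `c`'s.  Containment is order- and multiplicity-insensitive —
"contained all words" names words, not positions.  Levels are word
counts capped at 4; a node may have several parents ("infected wound"
descends from both "wound" and "infected").  The package stores the
*transitive closure* directly as an ancestor index: for feature rollup
the closure is what matters, and adjacent-level edge lists can be
derived from it (`export_hierarchy_edges()` exports the closure, which
is noted in its documentation).

`text_features()` rolls each occurrence up to every closure node on a
selected level; `expand_icd()` and `expand_atc()` do the analogous
prefix rollup for codes.  The ICD chapter/section range table shipped
with the package is a compact embedded subset covering the code points
the generator emits plus the gynaecological-oncology neighbourhood;
codes outside it simply skip the section level, and the full
classification is deliberately not bundled.

## Feature matrices

`build_matrix()` assembles the sparse patients-by-features matrix.
Feature identifiers are type- and level-prefixed
(`TEXT:L1:…`, `ICD:section:C51-C58`, `LAB:cat:Hb::ABOVE`), so
provenance is total and namespaces never collide.  Lab results enter as
three-way reference-range outcomes with inclusive bounds (a value equal
to a bound is `WITHIN`, matching the clinical convention that the range
is the set of acceptable values).  Encodings:

| encoding | definition | default consumer |
|---|---|---|
| `count`  | raw occurrence counts | random forest, complement NB |
| `binary` | ever experienced | Bernoulli NB |
| `l2norm` | counts scaled to unit Euclidean row norm | linear SVM |
| `tfidf`  | counts × (1 + log((N+1)/(df+1))) | optional |

L2 (not L1) is the normalization default, and the tf-idf variant is
pinned to the smoothed form above purely for reproducibility; neither
choice is forced by the science, and both are configurable.  The default
ATC representation uses full codes only (the multilevel ATC rollup is
available but was not the better representation in the motivating
study), while ICD uses all four levels and text all four hierarchy
levels.

## Feature ranking

Three filter scores are implemented on the development partition only:
a two-sample t statistic on counts, and mutual information and Pearson
chi-square on presence/absence (the 2×2 scores need discrete cells; the
t-test is the one described in terms of means and variances of
occurrences).  The *informative set* is the features with strictly
positive score; `select_top()` takes a ceiling-sized top fraction of it,
by default 10% for all classifiers and 1% for the SVM.  "Rank above
zero" is read as strictly positive score, not as a significance cut.

One design choice deserves emphasis: the t statistic uses the **pooled
(Student)** variance rather than Welch's unequal-variance form.  At 1:10
imbalance the Welch denominator is dominated by the case group, and its
control-group standard error is tiny; rare background features observed
only among the ~10× more numerous controls then receive large |t| purely
as an artifact of group size, crowding case-enriched prevalence
contrasts out of the top ranks.  The pooled form's variance is
control-dominated, so features that are frequent among cases but rare
among controls — the kind a top-feature table reports — rank first.
This is also why the generator's intensity overdispersion matters
methodologically: volume-driven differences in common features carry
large within-group variance and are damped by any t-type score, while
prevalence contrasts are not.

Because ranking happens on the development partition and is then frozen,
test-partition labels cannot influence selection; the test suite checks
this by permuting test labels and asserting the ranking is bit-identical.

## Evaluation

Four classifier configurations are fixed, each bound to its encoding:
random forest (`ranger`, counts), complement naive Bayes (counts),
Bernoulli naive Bayes (binary), and a linear SVM (`e1071`, L2-normalized
counts).  The two naive Bayes variants are implemented in the package as
small sparse-matrix log-linear scorers (with Laplace smoothing; the
complement form scores each class against its complement's multinomial,
which keeps it stable under imbalance) because no installed R library
provides the complement/Bernoulli multinomial family; both are verified
against hand-computed posteriors in the tests.

`crossvalidate()` performs stratified patient-level 10-fold
cross-validation.  Stratification is not optional at 1:10 imbalance —
unstratified folds can contain no cases at all, which the function
treats as an error rather than silently degrading.  Per-fold AUC is
computed from continuous scores (`pROC`); precision, recall, F1 and
specificity come from label predictions at each classifier's default
decision rule.  Summary precision/recall/F1/specificity pool the fold
confusion matrices, which keeps F1 exactly the harmonic mean of the
stored precision and recall; AUC is the mean of fold AUCs.
`sweep_evaluation()` repeats this per cutoff with per-cutoff rankings,
and `average_auc()` / `auc_series()` aggregate across the four
classifiers for event-type and level comparisons.

Default hyperparameters come from the underlying libraries (500 trees,
SVM cost 1, Laplace α = 1), with a pass-through `hyper` hook; the
package deliberately implements no tuning search.

## Numerical and degenerate-input choices

* Edit distance is delegated to `utils::adist` (a C Wagner–Fischer
  implementation); the test suite certifies it against an independent
  vectorised DP oracle exhaustively on all string pairs of length ≤ 6
  over a three-letter alphabet, with the oracle itself validated against
  the plain recursive definition on shorter strings.
* Zero-variance features with different means would make any t
  statistic infinite; scores are capped at the largest finite double so
  rankings stay finite and sortable.  `0·log 0 = 0` in the MI plug-in;
  constant features score 0 under chi-square rather than NaN.
* Frequency ties in canonical-form choice, score ties in rankings, and
  fold assignment are all broken deterministically (lexicographic order,
  fixed seeds), so identical inputs give byte-identical outputs.
* Empty inputs: an empty cohort request returns an empty cohort; an
  empty feature universe is an error advising to relax pruning; an
  empty informative set yields an empty selection with a warning.

## Problem sizes used by the tests

The default study conditions — 100 cases, 1000 controls, 20 planted
events, a 6000-surface background vocabulary — are what the acceptance
checks run end to end.  Unit tests use smaller cohorts (20–30 cases,
vocabularies of a few hundred surfaces) where the property under test
does not depend on scale.  On these sizes the full suite completes in a
few minutes on one CPU.

## Known limitations

* Because censoring shortens case streams while control streams are
  never truncated, the volume channel itself carries label information
  in the synthetic design; AUC therefore need not decline monotonically
  across *intermediate* horizons, and the package's monotonicity
  property compares the extreme horizons (1 versus 344 days).
* Recovery and AUC statements are about the generator's planted
  structure; transfer to real EHRs depends on how well the generator's
  assumptions (independent events, exponential signal timing,
  Zipf-shaped vocabulary) hold there.
* Chain-linked spelling groups can occasionally merge distinct rare
  terms; the normalization map export exists so such merges can be
  audited.
* The embedded ICD section table is a subset; section-level features
  for exotic codes are skipped rather than approximated.
* Recursive feature elimination and any NER/embedding machinery are
  intentionally out of scope.
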