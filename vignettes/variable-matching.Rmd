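---
title: "Matching variables across study dictionaries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching variables across study dictionaries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varmatchr)
```

## The task and the model

Retrospective harmonization of cohort studies begins by aligning
variables that measure the same construct.  `varmatchr` frames this as
learning-to-rank: for each source-study variable, every target-study
variable is a candidate, and candidates are ordered by an estimated
match probability.  The assumptions are modest but worth stating:

* the *data dictionaries* carry enough text to identify a construct —
  a human-readable label per variable, a short description per data
  sheet, and (often) a free-text derivation rule;
* matched variables share *lexical* signal (common technical terms) or
  *semantic* signal (different words, related meaning), so combining a
  fuzzy string scorer with embedding-based scorers covers both;
* curated example matches exist for training (a few hundred pairs), and
  a source variable may legitimately match several targets, e.g. the
  same construct recorded in multiple sheets.

Each variable is expanded into three text channels: `label`, `sheet`
(its data sheet description), and `label_key` — the label concatenated
with the derivation rule, or with keywords extracted from it when the
rule exceeds 20 words (rules at or below 20 words are kept verbatim).
Keyword extraction scores candidate 1–2-grams by cosine similarity of
their embedding to the whole rule's embedding and selects greedily,
skipping any phrase containing an already-selected word, under a
15-word budget.  The budget is interpreted as a cap on *total words*
across selected phrases; the greedy duplicate-word rule is our
documented choice where several reasonable variants exist.

Five scorers apply to every channel: four sentence-embedding backends
(cosine similarity on raw channel text) plus token-set-ratio fuzzy
matching on normalized text.  The resulting 15 similarity scores and 6
metadata features (label lengths, rule lengths, rule-absence flags for
both sides) feed a random-forest classifier whose positive-class
probability ranks the candidates.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| keyword budget `max_keywords` | 15 words | compresses long rules while keeping labels dominant |
| rule length threshold `word_limit` | 20 words | short rules carry little noise; keep them verbatim |
| negatives per positive `k_negatives` | 200 | tames a ~1:1300 class imbalance while keeping diverse negatives; capped at the available pool |
| train fraction | 0.8 (4:1) | standard split; `floor(0.8 N)` sources train |
| CV folds | 5, grouped by source | ranking metrics need whole candidate groups per fold |
| selection metric | HR-30 (or MRR) | matches how the ranking is consumed (top-*n* review lists) |
| forest grid | trees {100,300,500}; depth {unbounded,10,20}; split rule {gini, extratrees}; min node size {2,10}; mtry {sqrt(p), p/2} | a small grid around library defaults; all five dimensions configurable |
| embedding dim (offline backends) | 256 | enough buckets that trigram collisions are rare for short labels |

Fuzzy scores stay on their native 0–100 scale and embedding cosines on
[-1, 1]; tree ensembles are scale-invariant, so no feature scaling is
applied.

## Ranking, ties, and metrics

Candidates are ordered by descending score.  A block of `k` equal
scores occupying sorted positions `p..p+k-1` receives the block's
median rank `(2p+k-1)/2` for every member — so three candidates tied at
positions 4–6 all rank 5, and a top-two tie ranks both 1.5.  `HR-n` is
the fraction of evaluated sources whose best truth target has rank
`<= n` (strict: a tie-block rank of 30.5 is not a hit at n = 30 — a
documented choice, since no convention dictates the boundary case).
`MRR` averages `1 / R_hit`, with fractional ranks from tie resolution
used as-is.  For multi-match sources, `R_hit` is the smallest rank among
all truth targets — a hit requires any one of them.

## The experiment protocol

Per trial: split matched sources 4:1 (by source variable, never by
pair, so no pair involving a test source can leak into training);
down-sample negatives per positive instance, excluding *all* truth
targets of that source and never duplicating a negative within a
source; tune the forest by grouped-CV grid search; refit; rank the full
candidate list (no down-sampling at test time) per test source.
Within CV folds the validation metric is computed on the fold's own
down-sampled candidate sets — full candidate sets per fold would
dominate the runtime without changing the argmax in our experience, and
the choice is recorded here rather than hidden.

Trial seeds derive deterministically from a master seed and the trial
id (kept inside the 32-bit integer range), so a whole experiment —
splits, sampling, fold draws, forest fits, predictions — is
bit-reproducible, and an ablation rerun under the same master seed
reuses identical splits.

Analysis across trials: paired two-sided t-tests with t-based
confidence intervals (a zero-variance difference is flagged
`degenerate` with `p = NA` rather than raising); permutation importance
shuffles one feature column across the whole held-out table (globally,
not within source groups), `n_repeats` = 5 by default, and reports the
mean decline per metric — negative declines are legitimate; importances
aggregate both as mean decline over trials and as mean within-trial
rank (ties averaged).  Ablation removes one of three groups —
embedding-derived (12), fuzzy-derived (3), other (6) — which must
partition the feature set.

## The synthetic corpus

Real harmonization corpora are typically access-restricted, so the
generator builds a dictionary pair with known truth from a shared
concept pool (demographics, vitals, questionnaire items, costs,
time-to-event, comorbidities).  It emulates the features that make the
task hard and measurable:

* divergent naming conventions and label styles (verbose source labels,
  mean ~11.3 words, vs terser target labels, ~8.5);
* label corruption channels — per-word synonym swaps (0.15), word drops
  (0.08), whole-label shuffles (0.10), abbreviation substitutions
  (0.30) — applied independently to both sides of a matched concept;
* heavy derivation-rule missingness on the source side (72.6%) vs light
  on the target side (11.5%), with longer target rules (mean 26.4 vs
  14.9 words) so the keyword extractor is actually exercised;
* rule *wording* that is study-specific: each side draws from its own
  clause vocabulary and shares only the concept's core words, since two
  studies never phrase their definitions from a common template;
* one-to-many truth (a fifth of matched sources carry 2–3 targets in
  different sheets) and distractor targets built from held-out concepts;
* a long-format questionnaire sheet with its wide counterpart, so the
  long-to-wide transform is testable end to end.

Canonical (pre-noise) labels are generated deterministically per
concept, so in the zero-noise limit matched labels coincide exactly —
a useful boundary for tests.  What the generator does *not* emulate:
multilingual text, typos/OCR noise, ontology-grade synonymy beyond its
bundled word lists, or realistic data values (only the long-format
sheet needs values, and only structurally).  Passing tests on this
corpus therefore show that the machinery recovers planted lexical and
semantic signal under controlled corruption — not that any particular
pretrained embedding will succeed on a given real corpus.

The standard test conditions are 60 source and 240 target variables,
10 trials, k = 200 (capped at the ~237-candidate pool), and a
cross-validated choice of mtry in {sqrt(p), p/2}; these sizes keep the
full protocol — including a label-permuted negative control and
permutation importance with per-trial fresh noise columns — comfortably
desk-scale while leaving ranking room (top-30 of 240) for the metrics
to discriminate.

## Numerical and implementation choices

* **Median-rank ties** are computed as average ranks over tie blocks
  (identical to the median for consecutive positions), and probability
  ties are never broken by target order.
* **Fuzzy normalization** stems to a *fixpoint*: single-pass Porter is
  not idempotent for every word ("circumference" → "circumfer" →
  "circumf"), and the normalizer guarantees `f(f(x)) = f(x)`.  The
  stop-word list ships as a frozen fixture so normalized strings are
  stable across library versions.
* **Indel distance** inside the token-set ratio is computed as a
  generalized edit distance with substitution cost 2; for the two
  prefix-aligned string pairs the distance reduces to a length
  difference in closed form.  An independent dynamic-programming oracle
  cross-checks both in the tests.
* **Offline embedders** hash character trigrams into signed buckets
  with pure double-precision integer arithmetic (exact below 2^53), so
  vectors are identical across platforms; empty text embeds to the zero
  vector with a warning, and cosine against a zero vector is defined
  as 0.
* **Degenerate inputs**: all-stop-word text normalizes to `""` and
  scores 0 on the fuzzy channel; an empty candidate score set, NaN
  scores, unknown backends, schema mismatches and non-partitioning
  ablation groups raise informative errors.
* Dictionaries are NFC-normalized and whitespace-trimmed at load;
  derivation-rule emptiness is preserved, never replaced by a
  placeholder.  Longitudinal visit-indexed variables are left in long
  format (visit numbers align across studies); only questionnaire
  key/value pairs are widened, with labels instantiated from a
  `{key}` template — the template mechanism is our generalization,
  since no standard dictates how transformed labels are worded.

## Limitations

English-only text processing; no spelling correction or ontology-based
expansion.  The offline hashing embedders measure character-overlap
similarity — they stand in for, but do not approximate, pretrained
transformer embeddings, and real-corpus performance depends on the
backends plugged in.  Scores from the forest are used for ranking only
and are not calibrated probabilities.  Dictionaries that differ wildly
in structure may need custom column mapping and preprocessing before
`read_dictionary()` applies.
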