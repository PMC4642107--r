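---
title: "Methods: network conversion and event re-ranking over bibliome-scale event extraction output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network conversion and event re-ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bibliome)
```

## Problem setting

Event extraction systems read biomedical text and emit *events*: typed,
trigger-anchored structures whose arguments (Theme, Cause) are gene/protein
mentions or other events. Two practical problems arise downstream. First,
nested event structures are awkward for network biology; analyses want a
typed, directed gene regulatory network (GRN). Second, extractors produce
false positives, and the only leverage a post-processor has is to remove
predictions — trading recall for precision. This package implements both
post-processing systems over standoff-formatted corpora, together with the
evaluation machinery (precision/recall/F and strict/relaxed Slot Error
Rate) and a synthetic bibliome generator that makes every stage testable.

Both systems exploit *bibliome-wide aggregation*: events are grouped across
documents into generalizations — at the **canonical** level after
lower-casing and stripping non-alphanumeric characters from gene symbols
(`canonicalize()`, e.g. `Esr-1` → `esr1`), and at the **normalized-id**
level after resolving symbols through a curated table. The `event_index`
stores, per generalization key and per directed gene pair, occurrence
counts and maximum confidences; these are the evidence features both the ML
conversion and the re-ranker consume.

## Network interpretation and rule-based conversion

`flatten_to_relations()` turns one event into pairwise relations:

* Binding over ≥ 2 gene Themes emits every unordered pair in *both*
  orientations with coarse type (None, Binding). Emitting one arbitrary
  orientation would make the downstream filter order-dependent; the
  entity-type filter selects the compatible orientation instead.
* A regulation-family event with a gene Cause emits one relation per
  reachable leaf target; descending through nested regulations composes
  layers by **sign multiplication** (Positive∘Negative = Negative,
  Negative∘Negative = Positive) with Unspecified absorbing everything. This
  is the standard polarity algebra; nothing in the source formalism forces
  a different composition rule.
* The relation confidence is the **minimum** along the event chain — the
  conservative choice: a relation extracted through an uncertain inner
  event is no more certain than that event. Negation flags propagate by OR.
* Per event, at most one relation per (agent, target) pair is kept (the
  highest-confidence path), so chain depth cannot inflate counts.

`map_type_rule()` applies the conversion table **top-down**, so "regulation
of Transcription/Gene expression → Transcription" takes precedence over the
polarity rows; row order is the only precedence evidence available, and any
other order would make the polarity rows unreachable for transcription
events. `filter_entity_types()` enforces slot compatibility (e.g. Binding
only between a Gene agent and a Protein target, excluding protein–protein
interactions). Surviving Binding edges are then **refactored** to
Transcription — binding evidence that passes the Gene→Protein filter is
transcription-factor/promoter binding — strictly after filtering, since the
filter must see the original Binding type. Finally `select_edges()` keeps
one edge per ordered pair through four sequential rules: (1) drop
Regulation when a more specific type is present; (2) between contradictory
Activation and Inhibition keep the type of the single highest-confidence
edge (ties resolve to Activation, then input order — documented so the
result is deterministic); (3) drop mechanism edges (Transcription, Binding)
when a regulatory edge remains; (4) break residual ties by confidence, then
lexicographic type order, then input order. Whether specificity could ever
let a mechanism edge beat a regulatory one is genuinely open in the source
material; the sequential reading used here reconciles both stated
preferences ("most specific type" and "mechanism only when no regulatory
edge") and is validated against a brute-force oracle in the tests.

A consequence worth stating prominently: because of the refactoring step
the converter **never outputs a Binding edge**, so a gold Binding edge is
structurally unrecoverable (it behaves like the Requirement type, which no
rule produces either; both are accepted in gold files and score as
deletions).

## ML-based and hybrid conversion

For every agent–target pair with at least one forward event, a feature
vector aggregates the index: event counts and maximal confidences per
coarse event type and in total, the same for the reverse direction, a
reverse-dominance indicator, and optionally one-hot agent/target entity
types. One binary C-SVC RBF classifier per GRN type is trained
(`train_type_classifiers()`), with `(C, γ)` selected by exhaustive grid
search over `C ∈ 2^{-5..15}`, `γ ∈ 2^{-15..3}` (the standard exponential
grids) maximizing mean F over stratified 5-fold cross-validation — F is the
scoring rule because it is well-defined per fold, unlike a corpus-level
slot error rate. Fold assignment is seeded, so training is deterministic.
Types with fewer positives or negatives than folds train at default
parameters with a warning; single-class types become constant predictors.

Two points were settled during development and matter for correctness:

* **The feature index spans the whole bibliome.** Raw counts scale with
  corpus size, so computing features from a restricted document subset
  shifts the feature distribution between training and prediction. Document
  restriction therefore only selects *candidate pairs*; the index always
  covers all documents passed in.
* **The hybrid entity filter tests every observed entity-type combination**
  of a pair, not a single majority vote. Reverse orientations of Binding
  mentions from the opposite edge can dominate a majority and veto a
  correctly classified edge; testing the predicted type against each
  observed (agent, target) combination is the pair-level lift of the
  rule-based per-relation filter.

In `hybrid` mode positively classified edges pass through the entity
filter, refactoring and edge selection; in `ml_full` mode the classifiers
(trained with entity-type features) replace the filter and only edge
selection runs. The candidate-edge confidence is the pair's forward maximal
event confidence — edge selection needs one, and the maximum is the natural
summary of repeated mentions.

## Per-sentence re-ranking and threshold regression

Candidates are labeled against gold events by a recursive structural
matcher (`label_candidates()`): equal type, equal trigger span (an optional
±2-character tolerance flag exists for approximate-span conventions, off by
default), and equal argument multisets, entity arguments by span and type,
event arguments recursively; each gold event matches at most one prediction,
assigned greedily by confidence. The **sentence is the query set**: a
linear pairwise ranking model (`train_ranker()`) is fitted to
within-sentence (tp, fp) feature differences only — scores are never
compared across sentences. The reduction of ranking to classification over
preference-pair differences is the standard large-margin ranking
formulation; the underlying SVM is libSVM via e1071.

Features come in three switchable groups (`rerank_feature_config()`),
supporting ablations: *event* (extractor confidence, event type, argument
count, trigger-to-leaf role/type paths hashed into 8 categorical buckets),
*sentence context* (co-candidate count, their confidence statistics, type
histogram), and *bibliome* (exact generalization-key count and maximal
confidence per enabled level; a partial-match count over keys with the same
event type sharing at least one argument symbol, the exact key excluded;
and pairwise network counts for the candidate's flattened relations). On
synthetic corpora the index necessarily contains the scored corpus itself,
inflating every exact count by one — harmless for ranking, but worth
remembering when interpreting absolute feature values.

The per-sentence threshold target (`threshold_target()`) is the rank score
of the last event retained by the F-maximizing cut, found exhaustively over
the score-ordered cut points (only cuts realizable by a threshold are
considered, i.e. no ties across the cut; ties in F resolve toward the
larger retained set). Per-sentence F counts retained tp/fp and removed tp;
an empty retained set scores 1 when the sentence has no tp and 0 otherwise
— the boundary definition that makes "maximal F within the sentence"
well-defined. All-fp sentences get max score + 0.2, all-tp sentences min
score − 0.2; the 0.2 offset is the empirically established fallback margin.
A linear ε-insensitive regressor (`train_threshold_regressor()`) predicts
the target from sentence features: candidate count, score statistics, and —
because the target is by construction an order statistic of the sentence's
scores — the score deciles, which let a linear model express "cut at the
k-th order statistic" patterns. Defaults `cost = 1`, `ε = 0.1` favour a
smooth fit over chasing the noisy single-label fallback targets.

`run_rerank_experiment()` finally calibrates a **global shift** of the
predicted thresholds by maximizing filtered F on the training portion over
a fixed grid (−1.5 to 0.5 in steps of 0.05). This mirrors how the 0.2
fallback offset itself was established (empirically, on development data)
and compensates the asymmetric cost of regression error: a threshold
slightly too high removes true positives, which hurts F far more than a
slightly too low one that retains a false positive. Filtering cascades:
removing an event removes every event whose argument chain it breaks
(document-wide in `filter_corpus()`), so the output is always structurally
valid; cascading after thresholding, rather than modelling removals
jointly, follows from treating events as independent ranking instances.

Oracle harnesses bound the attainable performance: the best-case oracle
picks the F-maximizing threshold per sentence with gold access; the
worst-case oracle is forbidden from filtering all-fp sentences; the
random-ranking baseline replaces scores with uniform noise under the
worst-case oracle, averaged over 10 seeded runs. By construction
F(best) ≥ F(worst) exactly, and the margin of the re-ranked worst case over
the random one isolates the ranking's own contribution from the oracle's
gold access.

## Evaluation

`score_network()` pairs relations on the ordered identifier pair. Strict
mode counts a type mismatch on a gold pair as a substitution; relaxed mode
ignores types. SER = (S + I + D) / |gold|, the standard slot-error formula
with each substitution a full error; official shared-task scorers may
weight substitutions differently, so absolute SER values are comparable
only within this implementation. When several predictions land on one pair
(impossible after `select_edges()`, but allowed in the interface) the
highest-confidence one is paired and the rest are insertions. Ratios with
zero denominators (e.g. precision of an empty prediction) are defined as 1,
the vacuous-truth convention. `score_events()` reuses the structural
matcher and reports per-group breakdowns over the conventional GE groups:
Simple = {Gene_expression, Transcription, Localization}, Protein
modification = {Phosphorylation, Protein_modification, Ubiquitination,
Acetylation, Deacetylation}, Binding, and the Regulation family.

## The synthetic bibliome generator

`generate_bibliome()` plants a typed network over a synthetic gene
vocabulary and realizes each edge as `mentions_per_edge` event mentions
spread over documents (one sentence per line; several mentions may share a
sentence, which is what creates mixed query sets for the re-ranker).
Realizations are structurally diverse: direct regulations, nested
regulation-of-transcription/expression, double-nested regulation chains
exercising layer composition, and — for Transcription edges with Gene/
Protein slots — Binding events exercising the refactoring path. Gene
mentions use the standardized symbol or, at `variant_rate`, a lexical
variant: a case/punctuation variant that canonicalizes identically, or a
listed alias that only the symbol table resolves. False positives are
injected so their expected fraction equals `fp_rate`
(n_fp = round(n_true · fp/(1−fp)), deterministic, so the fraction
concentrates exactly); their realized coarse type is drawn from a
row-stochastic type-confusion matrix (uniform by default), their entity
types uniformly, and at `unmatched_symbol_rate` they use out-of-vocabulary
symbols. Confidences are Beta-distributed — Beta(5, 2) for true events,
Beta(2, 5) for false ones by default, so confidence correlates with
correctness, the property the re-ranker exploits; both are rounded to six
decimals so serialization round-trips bit-exactly.

The default conditions are 30 genes, 60 edges, 40 documents of 8 sentences,
3 mentions per edge, fp rate 0.3 — a corpus of a few hundred events, sized
so a scientist can run the full train/evaluate cycle in seconds while every
type and realization kind still occurs. The default type distribution gives
**Binding weight 0**: as explained above the converter can never produce a
Binding edge, so planting one would make perfect recovery structurally
impossible; Binding (like Requirement) can be planted explicitly to
exercise the evaluation path.

What the generator does *not* emulate: real syntax (templated clauses
only), entity-recognition errors (every mention is perfectly tagged —
missing or mis-spanned entities were a major error source in practice),
coordination and anaphora, cross-sentence events, correlated confusion
between specific type pairs, and realistic symbol ambiguity (one surface
form mapping to several genes). Passing tests therefore demonstrate the
correctness and internal consistency of the post-processing machinery under
controlled signal, not performance on real literature.

## Numerical and testing choices

Confidences live in (0, 1] and are carried in a sidecar TSV (standard .a2
has no confidence field; an absent sidecar defaults to confidence 1,
negation false). All randomness flows from explicit seeds: corpus
generation, CV folds, document splits, randomized rankings; identical seeds
give byte-identical corpora and identical trained models. Test problem
sizes were chosen as the smallest corpora in which every code path occurs
with margin: the oracle-ordering property uses 20 generator seeds of a
10-gene corpus with a one-sided sign test at the 5% level; the end-to-end
re-ranking check runs at the default generator conditions; brute-force
cross-checks (edge selection, slot-error enumeration, threshold search,
polarity composition up to depth 3) run on hundreds of random instances.

## Known limitations

* SER semantics beyond this implementation (fractional substitution
  credit, official relaxed matching) are not reproduced; numbers are not
  directly comparable to shared-task leaderboards.
* The ML conversion aggregates entity types per pair; per-mention entity
  disagreement is resolved by the any-compatible-combination rule in
  hybrid mode and by majority vote in the reported edge annotation.
* The re-ranker's feature inventory is a reconstruction of the described
  three groups, not a replica of any particular system's feature file; the
  feature-group switches exist precisely so ablations can quantify each
  group's contribution.
* Negated events are kept by default (matching the original conversion
  behaviour, which ignored negation contexts); `drop_negated = TRUE` is the
  documented fix.
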