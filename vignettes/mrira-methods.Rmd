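---
title: "Measuring multi-layer annotation agreement on medication-incident narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multi-layer annotation agreement on medication-incident narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrira)
```

## What the package models

Medication-safety incident narratives are annotated on four interacting
layers: typed entity spans, trigger-anchored events with role-labelled
arguments, directed entity relations with typed endpoint constraints, and
event attributes (negation and four mutually exclusive intent/actuality
labels). `mrira` provides the data model and standoff I/O for such
documents, a declarative schema with a validator, an inter-annotator
agreement (IAA) engine, corpus statistics, and a synthetic corpus generator
with a controllable annotator-disagreement model. The generator exists
because real incident-report corpora are access-restricted: every statistical
property of the agreement engine is therefore demonstrated on simulated
annotators with *known* disagreement rates, where the right answer can be
computed in closed form.

## Conventions of the standoff representation

Offsets are 0-based, half-open character offsets counted in Unicode code
points, the native convention of the standoff annotation tools this format
comes from. Discontinuous spans are ordered, non-overlapping fragment lists
(`"0 4;10 14"`); their surface is the fragment texts joined by single
spaces. The surface stored on a text-bound line must equal the surface
recomputed from the offsets — a mismatch is a hard parse error, because it
means the offsets index a different text than the one supplied. Since the
surface lives in a single-line tab-separated field, tabs and newlines inside
a span are normalised to spaces in the stored surface. Event triggers are
kept in the entity collection, as the standoff dialect does, but are
excluded from the entity scoring layer (they are scored with their events).
Annotator-note lines (`#`) round-trip verbatim and are ignored by validation
and scoring. The parser accepts structurally sound but scheme-invalid files
(e.g. an attribute on an entity) so that they can be loaded, diagnosed and
reported; conformance is the validator's job, which reports a closed set of
rule codes rather than throwing.

Two label-inventory details are worth calling out. First, several types
circulate under variant spellings (`Dosage form` vs `Drug form`,
`Patient age` vs `Age group`, `Frequency` vs `Drug frequency`); the schema
carries an alias table and every API alias-resolves before comparing labels,
so two annotators using different spellings of the same type still agree.
Second, intent/actuality is modelled as four mutually exclusive binary
attributes; a valued form (`Intent E1 Action intent not clear`) is accepted
on input and normalised to the binary form. An optional event-to-event
`Mismatch` link (for discrepancies such as *prescribed oral, administered
IV*) can be enabled in the schema; it is off by default and never counted
among the nine entity-relation types.

## The agreement model

One annotator is designated the reference, the other the response. For a
layer with `matched` one-to-one matched annotations, precision is
`matched / n_response`, recall is `matched / n_reference`, and F1 is their
harmonic mean. Under **strict** matching two annotations match when their
fragment lists are identical and their types equal; under **relaxed**
matching when the types are equal and any fragments overlap by at least one
character.

**Alignment.** Counting matches requires pairing the two annotation sets
one-to-one. A greedy first-come pairing undercounts agreement whenever
overlaps cross, so `align_annotations()` solves the assignment problem
exactly: maximum-cardinality matching over the admissible pairs, preferring
larger total character overlap among maximum matchings, with a deterministic
tie-break toward earlier-starting reference spans. This is implemented as
maximum-weight bipartite matching with weights `K + overlap + ε`, where `K`
exceeds the total overlap in the instance (so one extra pair always beats
any overlap gain) and `ε` encodes the tie-break without ever outweighing one
character of overlap. An exhaustive oracle (`brute_force_align()`)
enumerates all matchings on instances of ≤ 12 annotations; the test suite
and acceptance script verify the optimal aligner agrees with it on 1,000
random instances. Whether the original manual-annotation studies paired
greedily or optimally is generally not reported; scores computed here are
therefore comparable to published figures only up to that choice, which is a
documented caveat, not a knob.

**Layer composition.** Relations match only if their type matches and both
endpoints are paired in the entity correspondence computed under the same
criterion; attributes match only if their name (and value, if any) matches
and their host events are paired. The entity correspondence is computed once
per document pair and criterion and reused, so the layers are mutually
consistent. The event layer scores triggers plus event types only;
role-labelled argument agreement is available separately as a diagnostic
(`score_event_arguments()`), since published layer definitions do not state
whether arguments enter the event score.

**Averaging.** "Averaged F1" can mean pooled counts (micro) or a mean of
per-document scores (macro); both are reported, with micro as the headline
because pooled counts are the standard for span F1 and are robust to short
documents. Empty layers score P = R = 1 at the document level (nothing to
find, nothing found wrongly); such documents are excluded from the macro
mean, and a layer empty in every document reports `NA`, never 0. Bands
follow the usual reading of span-task F1: above 0.80 high, 0.60–0.79
moderate, below 0.60 low, with 0.50–0.60 flagged "potentially acceptable"
for the event-like layers (events, attributes), which are known to score
lower. The boundary value 0.80 itself is read as moderate, 0.60 as moderate,
and 0.50/0.60 as inside the potentially-acceptable interval.

```{r bands}
classify_band(0.85, "entities")
classify_band(0.51, "attributes")
```

**Provable properties.** Because strict-admissible pairs are a subset of
relaxed-admissible pairs and denominators do not depend on the criterion,
relaxed F1 ≥ strict F1 holds for the entity and event layers by construction;
for the composed layers (relations, attributes) it is asserted empirically
over hundreds of noisy document pairs. Swapping reference and response swaps
precision and recall and leaves F1 unchanged; self-agreement is exactly 1.

## The synthetic corpus: what it emulates and what it does not

Documents are built from slot-filling sentence templates in the style of a
typical incident narrative ("The nurse administered 10 mg of morphine to the
patient on the busy ward at 08:00."), organised into the subsections used by
real reporting systems: a summary (always present) plus underlying factors,
actions taken, actions planned and outcome, each present with probability
`p_section` (default 0.7, reflecting that most real reports do not fill
every subsection). Because the text is assembled token by token, gold
offsets are exact and every emitted annotation is schema-valid; generation
is byte-reproducible under a fixed seed.

Type frequencies follow the long-tailed profile of a manually annotated
development corpus of controlled-drug incident reports: `People` dominates,
then `Drug name`, then temporal references. Concretely, each optional slot
appears with probability proportional to its configured weight relative to
`People`'s weight; the default weights are that corpus's per-type counts,
with two floors so that rare code paths are exercised: types observed zero
times there (`Monitoring`, `Dose duration`) get small positive weights, and
`Action taken` — absent from the published count table though part of the
scheme — is floored like `Other action`. Two deliberate infidelities follow
from the design: `People` is anchored in every sentence, so its share
exceeds its weight share; and section-anchored types (`Medical condition` in
outcomes, `Artefact` in actions) are likewise over-represented relative to
the exact table proportions. Tests therefore assert the frequency *ranking*
(`People` > `Drug name` > `Date/Time` > rare types), which the generator
preserves, not exact proportions. The generator makes no claim of linguistic
fidelity — report length and style distributions of real systems are only
qualitatively known — and none of clinical plausibility.

Harm levels (`low`, `moderate`, `high`, `unspecified`) are attached per
report for sampling experiments; `stratified_sample()` implements the
one-in-every-`k`-listed systematic design within harm strata that incident
registers use to draw screening pools.

## The disagreement model

A simulated second annotator is derived from gold by independent
per-annotation operators, mirroring the disagreement patterns reported
between real annotators:

| operator | rate | emulates |
|---|---|---|
| boundary jitter | `p_boundary` | span granularity ("morphine sulfate" vs "morphine") |
| attribute drop | `p_attr_drop` | attribute left unset by one annotator |
| relation retarget | `p_rel_retarget` | relation linked to a different compatible entity |
| relabel | `p_relabel` | confusions within similar-type sets |
| delete / insert | `p_delete`, `p_insert` | plain recall/precision noise |

Operators preserve schema validity by construction: deletions cascade (an
event dies with its trigger; relations lose deleted endpoints; attributes
die with their hosts), relabels that would break a relation's endpoint
constraint drop that relation, insertions are placed over unannotated words
(so they never coincide with a gold span under either criterion), and jitter
always keeps ≥ 1 character of overlap, always changes the span when any move
is feasible, moves a boundary by at most 3 characters, and never crosses a
line break — an annotator does not extend a span into the next subsection.
Boundary-only noise therefore leaves relaxed entity F1 at exactly 1.0 on
every seed, while breaking strict agreement.

For the deletion/insertion sub-model the expected micro scores have closed
forms (`expected_scores()`): entity recall `1 − d`, entity precision
`(1 − d) / (1 − d + i)`, event recall `1 − d`, relation recall `(1 − d)³`
(its own survival and both endpoints'), attribute recall
`(1 − d)(1 − a)` (host survival times its own drop rate), precision 1 on
layers with no insertions. No closed form is claimed — and the function
refuses — when boundary, relabel or retarget noise is active, because
matching then depends on span geometry.

```{r expected}
expected_scores(perturbation_config(p_delete = 0.2))
```

## Numerical and design choices

* **Problem sizes.** Parameter-recovery runs use 180 generated reports
  (≈ 2,200 gold entity mentions), where the binomial standard error of a
  recall near 0.8 is below 0.01, comfortably inside the ±0.02 tolerance
  asserted for the entities layer. The attribute layer is ~25× sparser at
  the same corpus size (its standard error alone is ≈ 0.05), so its
  Monte-Carlo check is asserted at ±0.05. Alignment-oracle equivalence uses
  1,000 instances of ≤ 10 annotations; monotonicity uses 500 document pairs
  under two mixed-noise settings.
* **Determinism.** All generation and perturbation flows through R's RNG
  under an explicit seed, with the caller's RNG state restored afterwards;
  corpus-level perturbation seeds once and processes documents in order.
  Alignment is deterministic including tie-breaks.
* **Degenerate inputs.** Empty annotation payloads parse to empty documents;
  an empty corpus summarises to all-zero rows (every schema type is always
  present in the statistics, including zero-count types); empty layers
  follow the 0/0 → 1 convention documented above; an empty report list is an
  error for scoring (there is nothing to average) but not for sampling.
* **Word counts.** Corpus statistics count whitespace-delimited tokens of
  the covered surface; hyphenated tokens are one word. Averages are reported
  exact and rounded, because published summary tables round. The per-type
  total-word column is interpreted as the summed token count over that
  type's annotations, consistent with rows whose rounded average times count
  undershoots the printed total; this interpretation is stated in the table
  footer the CLI emits.
* **What passing tests show.** Green parameter-recovery and monotonicity
  tests demonstrate that the *scoring machinery* is correct and unbiased
  under a known disagreement process. They do not certify any particular
  agreement level on real narratives, whose disagreement structure (nested
  events, implicit error types, fragmented sentences) is richer than the
  five operators modelled here.

## Known limitations

* Two annotators only; no chance-corrected coefficients (kappa) — span-based
  tasks conventionally use P/R/F1, and extending to k > 2 annotators or
  partial-credit weighting is out of scope.
* Relaxed overlap is ≥ 1 character with no proportional-overlap option
  (kept as a configuration hook, off by default).
* The optimal-vs-greedy pairing caveat above applies when comparing against
  externally published scores.
* Generated narratives are template text: adequate for exercising offsets,
  schema constraints and scoring, inadequate as NLP training data.
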