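# mrira

Multi-layer standoff annotation tooling for medication-incident narratives:
schema validation, inter-annotator agreement, corpus statistics, and a
synthetic annotated-corpus generator.

## The problem

Free-text incident reports — the narratives clinicians write when a
medication error occurs — carry the causal detail (who did what, with which
drug, at what dose, with what outcome) that structured reporting fields drop.
Mining them requires an annotation scheme and, before any model is trained,
evidence that two humans can apply that scheme consistently.

`mrira` implements the MRIRA (Medication-Related Incident Report Annotation)
scheme as executable software. The scheme is multi-layered:

* **Entities** — 16 types: general (`People`, `Location`, `Date/Time`,
  `Artefact`, `Knowledge`, `Function`), patient-specific (`Age group`,
  `Gender`) and domain-specific (`Drug name`, `Drug form`,
  `Drug strength or amount`, `Drug dose`, `Drug frequency`, `Dose route`,
  `Dose duration`, `Medical condition`).
* **Events** — 11 types anchored to a trigger span: the 5 main
  medication-use stages (`Prescribing`, `Transcription`, `Dispensing`,
  `Administration`, `Monitoring`) plus 6 supplementary types
  (`Corrective action`, `Preventive action`,
  `Underlying and contributing factors`, `Error outcome`, `Action taken`,
  `Other action`), with 6 argument roles (`Agent`, `Subject`, `Receiver`,
  `When`, `Where`, `For`).
* **Relations** — 9 directed entity-relation types with typed endpoint
  constraints (e.g. `has dose: Drug name → Drug dose`; `has frequency` may
  start from `Drug name` or `Drug dose`).
* **Attributes** — 5 event modifiers: four mutually exclusive
  intent/actuality labels and `Negated`.

Documents are plain text plus BRAT-style standoff annotations (`.txt`/`.ann`
pairs; offsets are 0-based, half-open, counted in Unicode code points).

## Inter-annotator agreement

Given the same narrative annotated by a *reference* and a *response*
annotator, agreement per layer is measured with precision, recall and F1:

```
P = matched / n_response,  R = matched / n_reference,  F1 = 2PR / (P + R)
```

where `matched` is the size of an **optimal one-to-one alignment** between
the two annotation sets (maximum cardinality, ties broken by character
overlap — never greedy first-come pairing, which undercounts crossing
overlaps). Two matching criteria are supported:

* **strict** — span boundaries and label identical;
* **relaxed** — labels identical, spans overlapping by ≥ 1 character.

Layers are scored compositionally: a relation matches only if its type
matches and *both endpoints are aligned* in the entity correspondence; an
attribute matches only if its name matches and its *host events are
aligned*. F1 values are banded (> 0.80 high, 0.60–0.79 moderate, < 0.60
low; 0.50–0.60 flagged "potentially acceptable" for the event-like layers).

Because real incident reports are access-restricted, the package also ships
a synthetic-corpus generator (template narratives with exact gold offsets)
and a parameterised disagreement model (`p_delete`, `p_insert`,
`p_boundary`, `p_relabel`, `p_attr_drop`, `p_rel_retarget`) whose
deletion/insertion sub-model has closed-form expected scores — so the whole
agreement engine is testable by parameter recovery.

## Worked example

```r
library(mrira)

dir <- system.file("extdata", "example-corpus", package = "mrira")
doc <- read_corpus(dir)[[1]]
doc
#> <mrira_document 'incident_example': 271 chars, 19 entities, 6 events, 5 relations, 3 attributes>

validate_document(default_schema(), doc)   # 0 rows: scheme-conformant

# simulate a second annotator who jitters half the span boundaries and
# forgets half the attributes
noisy <- perturb_document(
  doc, perturbation_config(p_boundary = 0.5, p_attr_drop = 0.5, seed = 42)
)
rep <- score_corpus(list(list(reference = doc, response = noisy)))
rep$corpus[rep$corpus$average == "micro",
           c("layer", "criterion", "matched", "precision", "recall", "f1", "band")]
#>   layer     criterion matched precision recall    f1 band
#> 1 entities  strict          7     0.538  0.538 0.538 low
#> 2 relations strict          0     0      0     0     low
#> 3 events    strict          3     0.5    0.5   0.5   low
#> 4 attributes strict         0     1      0     0     low
#> 5 entities  relaxed        13     1      1     1     high
#> 6 relations relaxed         5     1      1     1     high
#> 7 events    relaxed         6     1      1     1     high
#> 8 attributes relaxed        0     1      0     0     low
```

Reading the output: boundary jitter destroys exact span matches (strict
entity F1 drops to 0.538) but preserves overlap, so relaxed agreement stays
perfect — and the relations layer collapses under strict matching because
its endpoint entities are no longer aligned. The dropped attributes cost
recall only: the response asserted nothing wrong, so precision stays 1.

The same operations are available from the shell:

```sh
mrira=$(Rscript -e 'cat(system.file("cli", "mrira", package = "mrira"))')
$mrira generate --config gen.yaml --out gold/
$mrira perturb  --gold gold/ --config noise.yaml --out annotator2/
$mrira agree    --ref gold/ --res annotator2/ --out report.json
$mrira validate --corpus gold/
$mrira stats    --corpus gold/ --out table.csv
```

## Package layout

* `R/` — standoff I/O, schema + validator, alignment, agreement, corpus
  statistics, synthetic generator + disagreement model, CLI dispatcher.
* `inst/extdata/mrira-schema.yaml` — the bundled scheme (swappable: any
  schema in the same YAML layout can be passed to the validator and scorer).
* `inst/extdata/example-corpus/` — a small fully annotated worked example.
* `vignettes/mrira-methods.Rmd` — models, conventions, design decisions and
  known limitations.
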