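Package: mrira
Title: Multi-Layer Annotation, Validation and Inter-Annotator Agreement for
    Medication-Incident Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with multi-layer standoff annotations of
    medication-related incident report narratives. Implements the MRIRA
    (Medication-Related Incident Report Annotation) type system as a
    declarative, swappable schema; reads and writes BRAT-style standoff
    annotation files (entities, events, relations, attributes) losslessly;
    validates documents against the schema's type inventory and relation
    endpoint constraints; computes inter-annotator agreement (precision,
    recall, F1) per annotation layer under strict and relaxed span-matching
    criteria using optimal one-to-one alignment; summarises annotated corpora;
    and generates synthetic annotated incident narratives with a
    parameterised annotator-disagreement model so the agreement machinery can
    be exercised without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
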