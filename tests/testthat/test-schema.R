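test_that("the default scheme has the published inventory sizes", {
  sch <- default_schema()
  expect_equal(
    schema_counts(sch),
    c(
      entity_types = 16L, event_types = 11L, attribute_types = 5L,
      relation_types = 9L, argument_roles = 6L
    )
  )
  expect_equal(
    table(sch$entity_types$group)[c("general", "patient_specific", "domain_specific")],
    table(factor(c(
      rep("general", 6), rep("patient_specific", 2), rep("domain_specific", 8)
    )))[c("general", "patient_specific", "domain_specific")]
  )
  expect_true("Monitoring" %in%
    sch$event_types$name[sch$event_types$group == "main"])
  expect_setequal(
    sch$argument_roles, c("Agent", "Subject", "Receiver", "When", "Where", "For")
  )
  # repeated construction is pure
  expect_equal(default_schema(), sch)
})

test_that("'has frequency' allows exactly its two endpoint pairs", {
  sch <- default_schema()
  hf <- sch$relations[sch$relations$name == "has frequency", ]
  expect_equal(nrow(hf), 2L)
  expect_setequal(hf$source, c("Drug name", "Drug dose"))
  expect_equal(unique(hf$target), "Drug frequency")
})

test_that("variant spellings resolve to canonical labels; unknowns are flagged", {
  sch <- default_schema()
  cases <- c(
    "Dosage form" = "Drug form",
    "Strength or amount" = "Drug strength or amount",
    "Dose" = "Drug dose",
    "Frequency" = "Drug frequency",
    "Dose frequency" = "Drug frequency",
    "Route of administration" = "Dose route",
    "Duration" = "Dose duration",
    "Patient age" = "Age group",
    "Date or time" = "Date/Time",
    "Underlying or contributing factor" = "Underlying and contributing factors",
    "Other actions" = "Other action",
    "Has dose" = "has dose",
    "has_route" = "has route",
    "Drug name" = "Drug name" # canonical is identity
  )
  got <- resolve_type_alias(sch, names(cases))
  expect_equal(as.vector(got), unname(cases))
  expect_false(any(attr(got, "unknown")))

  odd <- resolve_type_alias(sch, "Banana")
  expect_equal(as.vector(odd), "Banana")
  expect_true(attr(odd, "unknown"))
})

test_that("a schema survives a YAML write/read round trip", {
  sch <- default_schema()
  path <- file.path(withr_like_tempdir(), "scheme.yaml")
  write_schema(sch, path)
  back <- read_schema(path)
  expect_equal(schema_counts(back), schema_counts(sch))
  expect_equal(back$relations, sch$relations)
  expect_equal(back$aliases, sch$aliases)
})

test_that("relation endpoint constraints are enforced", {
  sch <- default_schema()
  text <- "nurse gave 10 mg"
  ann <- paste(
    "T1\tPeople 0 5\tnurse",
    "T2\tDrug dose 11 16\t10 mg",
    "R1\thas dose Arg1:T1 Arg2:T2",
    sep = "\n"
  )
  v <- validate_document(sch, parse_document(text, ann, "bad-endpoint"))
  expect_equal(nrow(v), 1L)
  expect_equal(v$rule, "relation_endpoint_type")
  expect_equal(v$ann_id, "R1")

  # the allowed pair passes
  ok <- sub("People", "Drug name", ann, fixed = TRUE)
  expect_equal(
    nrow(validate_document(sch, parse_document(text, ok, "ok-endpoint"))), 0L
  )
})

test_that("the worked-example fixture is fully scheme-conformant", {
  v <- validate_document(default_schema(), example_doc())
  expect_equal(nrow(v), 0L)
  # and an empty document trivially is
  expect_equal(
    nrow(validate_document(default_schema(), mrira_document("e", "text"))), 0L
  )
})

test_that("unknown labels, bad hosts and trigger mismatches are each reported", {
  sch <- default_schema()
  text <- "nurse gave morphine now"
  ann <- paste(
    "T1\tRobot 0 5\tnurse", # unknown entity type
    "T2\tAdministration 6 10\tgave",
    "T3\tDrug name 11 19\tmorphine",
    "E1\tPrescribing:T2 Pilot:T3", # type != trigger type; unknown role
    "A1\tNegated T3", # attribute on an entity
    "A2\tShouted E1", # unknown attribute
    "R1\tbefore Arg1:T1 Arg2:T3", # unknown relation type
    sep = "\n"
  )
  v <- validate_document(sch, parse_document(text, ann, "messy"))
  expect_setequal(
    v$rule,
    c(
      "unknown_entity_type", "trigger_type_mismatch", "unknown_argument_role",
      "attribute_host_kind", "unknown_attribute_name", "unknown_relation_type"
    )
  )
})

test_that("the four intent/actuality attributes are mutually exclusive", {
  text <- "dose given"
  ann <- paste(
    "T1\tAdministration 5 10\tgiven",
    "E1\tAdministration:T1",
    "A1\tAction intended and actual E1",
    "A2\tAction intent not clear E1",
    sep = "\n"
  )
  v <- validate_document(default_schema(), parse_document(text, ann, "twoflags"))
  expect_equal(v$rule, "intent_attribute_conflict")
  expect_equal(v$ann_id, "E1")
})

test_that("a valued intent attribute normalises to the binary form", {
  text <- "dose given"
  ann <- paste(
    "T1\tAdministration 5 10\tgiven",
    "E1\tAdministration:T1",
    "A1\tIntent E1 Action intent not clear",
    sep = "\n"
  )
  doc <- parse_document(text, ann, "valued")
  resolved <- resolve_document(doc, default_schema())
  expect_equal(resolved$attributes$A1$name, "Action intent not clear")
  expect_null(resolved$attributes$A1$value)
  expect_equal(nrow(validate_document(default_schema(), doc)), 0L)
})

test_that("validation is order-independent up to permutation", {
  sch <- default_schema()
  doc <- example_doc()
  # corrupt one relation so there is something to report
  doc$relations$R1$target <- doc$relations$R2$target
  v1 <- validate_document(sch, doc)
  lines <- strsplit(serialize_document(doc), "\n", fixed = TRUE)[[1]]
  set.seed(1)
  doc2 <- parse_document(doc$text, paste(sample(lines), collapse = "\n"), doc$doc_id)
  v2 <- validate_document(sch, doc2)
  expect_equal(v1[order(v1$ann_id, v1$rule), ], v2[order(v2$ann_id, v2$rule), ])
  expect_gt(nrow(v1), 0L)
})
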