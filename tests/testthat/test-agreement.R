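test_that("precision, recall and F1 follow the count formulas", {
  expect_equal(unname(compute_prf(3, 4, 4)), c(0.75, 0.75, 0.75))
  expect_equal(unname(compute_prf(1, 1, 2)), c(0.5, 1, 2 / 3))
  # empty-layer convention: nothing to find, nothing found wrongly
  expect_equal(unname(compute_prf(0, 0, 0)), c(1, 1, 1))
  expect_equal(unname(compute_prf(0, 3, 0)), c(1, 0, 0))
  expect_error(compute_prf(5, 4, 4), "exceeds")
  expect_error(compute_prf(-1, 4, 4))
})

test_that("self-agreement is exactly 1 on every layer and criterion", {
  doc <- example_doc()
  for (layer in c("entities", "relations", "events", "attributes")) {
    for (crit in c("strict", "relaxed")) {
      s <- score_layer(doc, doc, layer, crit)
      expect_equal(s$precision, 1)
      expect_equal(s$recall, 1)
      expect_equal(s$f1, 1)
      expect_gt(s$n_reference, 0) # the fixture populates all four layers
    }
  }
})

test_that("a spurious and a missed entity move P and R as hand-counted", {
  # reference: 4 word entities; response reproduces 3 exactly, adds 1 new
  ref <- tiny_doc(c(
    "T1\tDrug name 0 2\taa",
    "T2\tDrug dose 3 5\tbb",
    "T3\tPeople 6 8\tcc",
    "T4\tLocation 9 11\tdd"
  ))
  res <- tiny_doc(c(
    "T1\tDrug name 0 2\taa",
    "T2\tDrug dose 3 5\tbb",
    "T3\tPeople 6 8\tcc",
    "T5\tFunction 12 14\tee"
  ))
  s <- score_layer(ref, res, "entities", "strict")
  expect_equal(s$matched, 3L)
  expect_equal(s$precision, 0.75)
  expect_equal(s$recall, 0.75)
  expect_equal(s$f1, 0.75)
})

test_that("a negated event left unflagged costs attribute recall, not precision", {
  base <- c(
    "T1\tMedical condition 12 14\tee",
    "T2\tError outcome 0 2\taa",
    "E1\tError outcome:T2 Subject:T1"
  )
  ref <- tiny_doc(c(base, "A1\tNegated E1"))
  res <- tiny_doc(base)
  for (crit in c("strict", "relaxed")) {
    s <- score_layer(ref, res, "attributes", crit)
    expect_equal(s$matched, 0L)
    expect_equal(s$recall, 0)
    expect_equal(s$precision, 1) # response asserted nothing wrong
  }
  # the events themselves still agree perfectly
  expect_equal(score_layer(ref, res, "events", "strict")$f1, 1)
})

test_that("relations only match when both endpoints are paired", {
  ref <- tiny_doc(c(
    "T1\tDrug name 0 2\taa",
    "T2\tDrug dose 3 5\tbb",
    "R1\thas dose Arg1:T1 Arg2:T2"
  ))
  # same relation type, but the response put the dose span elsewhere:
  # under strict the dose entities are unmatched, so the relation cannot match
  res <- tiny_doc(c(
    "T1\tDrug name 0 2\taa",
    "T2\tDrug dose 9 11\tdd",
    "R1\thas dose Arg1:T1 Arg2:T2"
  ))
  expect_equal(score_layer(ref, res, "relations", "strict")$matched, 0L)
  # identical relation annotations match
  expect_equal(score_layer(ref, ref, "relations", "strict")$f1, 1)
})

test_that("attributes only match when their host events are paired", {
  ref <- tiny_doc(c(
    "T1\tAdministration 0 2\taa",
    "E1\tAdministration:T1",
    "A1\tNegated E1"
  ))
  # response hangs the same attribute on an event triggered elsewhere
  res <- tiny_doc(c(
    "T1\tAdministration 9 11\tdd",
    "E1\tAdministration:T1",
    "A1\tNegated E1"
  ))
  expect_equal(score_layer(ref, res, "attributes", "strict")$matched, 0L)
})

test_that("event scoring requires the event type, not just the trigger span", {
  ref <- tiny_doc(c("T1\tPrescribing 0 2\taa", "E1\tPrescribing:T1"))
  res <- tiny_doc(c("T1\tDispensing 0 2\taa", "E1\tDispensing:T1"))
  for (crit in c("strict", "relaxed")) {
    expect_equal(score_layer(ref, res, "events", crit)$matched, 0L)
  }
})

test_that("documents with different texts are not comparable", {
  a <- parse_document("text one", "", "a")
  b <- parse_document("text two", "", "b")
  expect_error(score_layer(a, b, "entities", "strict"), "not comparable")
})

test_that("corpus micro pools counts and macro averages per-document F1", {
  # pair 1: matched 3 / ref 4 / resp 4; pair 2: matched 1 / ref 2 / resp 2
  ref1 <- tiny_doc(c(
    "T1\tDrug name 0 2\taa", "T2\tDrug dose 3 5\tbb",
    "T3\tPeople 6 8\tcc", "T4\tLocation 9 11\tdd"
  ))
  res1 <- tiny_doc(c(
    "T1\tDrug name 0 2\taa", "T2\tDrug dose 3 5\tbb",
    "T3\tPeople 6 8\tcc", "T5\tFunction 12 14\tee"
  ))
  ref2 <- tiny_doc(c("T1\tPeople 0 2\taa", "T2\tPeople 3 5\tbb"), doc_id = "t2")
  res2 <- tiny_doc(c("T1\tPeople 0 2\taa", "T2\tPeople 9 11\tdd"), doc_id = "t2")
  rep <- score_corpus(list(
    list(reference = ref1, response = res1),
    list(reference = ref2, response = res2)
  ), criteria = "strict")
  micro <- rep$corpus[rep$corpus$layer == "entities" & rep$corpus$average == "micro", ]
  macro <- rep$corpus[rep$corpus$layer == "entities" & rep$corpus$average == "macro", ]
  expect_equal(micro$matched, 4L)
  expect_equal(micro$precision, 4 / 6)
  expect_equal(micro$recall, 4 / 6)
  expect_equal(macro$f1, (0.75 + 0.5) / 2)
  # micro counts equal sums of per-document counts
  per <- rep$per_document
  expect_equal(
    sum(per$matched[per$layer == "entities"]), micro$matched
  )
})

test_that("identical corpora score 1 everywhere; absent layers are NA, not 0", {
  doc <- example_doc()
  rep <- score_corpus(list(
    list(reference = doc, response = doc),
    list(reference = doc, response = doc)
  ))
  expect_true(all(rep$corpus$f1 == 1))

  bare <- tiny_doc("T1\tPeople 0 2\taa")
  rep2 <- score_corpus(list(list(reference = bare, response = bare)),
    criteria = "strict"
  )
  attr_rows <- rep2$corpus[rep2$corpus$layer == "attributes", ]
  expect_true(all(is.na(attr_rows$f1)))
  expect_true(all(is.na(attr_rows$band)))
  ent_rows <- rep2$corpus[rep2$corpus$layer == "entities", ]
  expect_true(all(ent_rows$f1 == 1))
})

test_that("swapping reference and response swaps P and R and preserves F1", {
  pairs <- random_scored_pairs(20, gen_seed = 31, perturb_seed = 32)
  for (pr in pairs[1:10]) {
    for (crit in c("strict", "relaxed")) {
      fwd <- mrira:::layer_counts(pr$reference, pr$response, crit, default_schema())
      rev <- mrira:::layer_counts(pr$response, pr$reference, crit, default_schema())
      for (layer in c("entities", "relations", "events", "attributes")) {
        a <- compute_prf(
          fwd[[layer]][["matched"]], fwd[[layer]][["n_reference"]],
          fwd[[layer]][["n_response"]]
        )
        b <- compute_prf(
          rev[[layer]][["matched"]], rev[[layer]][["n_reference"]],
          rev[[layer]][["n_response"]]
        )
        expect_equal(a[["precision"]], b[["recall"]])
        expect_equal(a[["recall"]], b[["precision"]])
        expect_equal(a[["f1"]], b[["f1"]])
      }
    }
  }
})

test_that("interpretation bands follow the conventional thresholds", {
  expect_equal(classify_band(0.85, "entities")$band, "high")
  expect_equal(classify_band(0.62, "events")$band, "moderate")
  low <- classify_band(0.51, "attributes")
  expect_equal(low$band, "low")
  expect_true(low$potentially_acceptable)
  # the flag is for event-like layers only
  expect_false(classify_band(0.51, "entities")$potentially_acceptable)
  expect_true(classify_band(0.55, "events")$potentially_acceptable)
  expect_false(classify_band(0.49, "events")$potentially_acceptable)
  expect_error(classify_band(1.2, "entities"), "0, 1")
  expect_equal(classify_band(NA_real_, "events")$band, NA_character_)
})

test_that("argument links can be scored as a separate diagnostic", {
  doc <- example_doc()
  s <- score_event_arguments(doc, doc, "strict")
  expect_equal(s$f1, 1)
  expect_gt(s$n_reference, 0)
  # dropping one argument from the response lowers recall only
  res <- doc
  res$events$E2$args <- res$events$E2$args[-1]
  s2 <- score_event_arguments(doc, res, "strict")
  expect_equal(s2$precision, 1)
  expect_lt(s2$recall, 1)
})
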