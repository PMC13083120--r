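test_that("generation is deterministic and every document is schema-valid", {
  cfg <- generator_config(seed = 21, n_reports = 8)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_equal(length(c1$documents), 8L)
  expect_identical(
    vapply(c1$documents, serialize_document, character(1)),
    vapply(c2$documents, serialize_document, character(1))
  )
  expect_identical(c1$harm_level, c2$harm_level)
  expect_equal(nrow(validate_corpus(default_schema(), c1$documents)), 0L)
  expect_true(all(c1$harm_level %in% c("low", "moderate", "high", "unspecified")))
})

test_that("an unsatisfiable generator config is rejected before generation", {
  voc <- default_vocabulary()
  voc$drugs <- character()
  expect_error(
    generator_config(vocabulary = voc),
    "Drug name.*drugs"
  )
  expect_error(generator_config(sections = "underlying"), "summary")
  expect_error(generator_config(p_section = 2))
})

test_that("a zero-rate perturbation is the identity and scores 1 everywhere", {
  gold <- generate_corpus(generator_config(seed = 13, n_reports = 4))
  pert <- perturb_corpus(gold, perturbation_config(seed = 14))
  for (b in names(gold$documents)) {
    expect_equal(pert[[b]], gold$documents[[b]])
  }
  rep <- score_corpus(lapply(names(gold$documents), function(b) {
    list(reference = gold$documents[[b]], response = pert[[b]])
  }))
  expect_true(all(rep$corpus$f1[!is.na(rep$corpus$f1)] == 1))
})

test_that("perturbed documents are always schema-valid and reproducible", {
  gold <- generate_corpus(generator_config(seed = 17, n_reports = 10))
  p <- perturbation_config(
    p_delete = 0.2, p_insert = 0.2, p_boundary = 0.5, p_relabel = 0.3,
    p_attr_drop = 0.5, p_rel_retarget = 0.5, seed = 18
  )
  pert1 <- perturb_corpus(gold, p)
  pert2 <- perturb_corpus(gold, p)
  expect_identical(
    lapply(pert1, serialize_document), lapply(pert2, serialize_document)
  )
  expect_equal(nrow(validate_corpus(default_schema(), pert1)), 0L)
})

test_that("boundary-only noise breaks strict but never relaxed entity agreement", {
  gold <- generate_corpus(generator_config(seed = 23, n_reports = 30))
  pert <- perturb_corpus(gold, perturbation_config(p_boundary = 1, seed = 24))
  rep <- score_corpus(lapply(names(gold$documents), function(b) {
    list(reference = gold$documents[[b]], response = pert[[b]])
  }))
  ent <- rep$corpus[rep$corpus$layer == "entities" & rep$corpus$average == "micro", ]
  expect_lt(ent$f1[ent$criterion == "strict"], 1)
  expect_equal(ent$f1[ent$criterion == "relaxed"], 1)
})

test_that("closed-form expected scores match their defining formulas", {
  none <- expected_scores(perturbation_config())
  expect_true(all(none$f1 == 1))

  del <- expected_scores(perturbation_config(p_delete = 0.2))
  ent <- del[del$layer == "entities", ]
  expect_equal(ent$precision, 1)
  expect_equal(ent$recall, 0.8)
  expect_equal(ent$f1, 8 / 9)
  expect_equal(del$recall[del$layer == "relations"], 0.8^3)

  both <- expected_scores(perturbation_config(p_delete = 0.2, p_insert = 0.25))
  ent2 <- both[both$layer == "entities", ]
  expect_equal(ent2$precision, 0.8 / 1.05)
  expect_equal(ent2$recall, 0.8)

  attr <- expected_scores(perturbation_config(p_delete = 0.2, p_attr_drop = 0.5))
  expect_equal(attr$recall[attr$layer == "attributes"], 0.8 * 0.5)

  expect_error(
    expected_scores(perturbation_config(p_boundary = 0.5)), "closed form"
  )
  expect_error(perturbation_config(p_delete = 1.5), "\\[0, 1\\]")
})

test_that("Monte-Carlo micro scores recover the configured noise rates", {
  gold <- generate_corpus(generator_config(seed = 41, n_reports = 180))
  n_gold <- sum(vapply(
    gold$documents, function(d) length(mrira:::non_trigger_entities(d)),
    integer(1)
  ))
  expect_gte(n_gold, 2000)
  p <- perturbation_config(p_delete = 0.2, p_insert = 0.25, seed = 42)
  pert <- perturb_corpus(gold, p)
  rep <- score_corpus(
    lapply(names(gold$documents), function(b) {
      list(reference = gold$documents[[b]], response = pert[[b]])
    }),
    criteria = "strict"
  )
  ent <- rep$corpus[rep$corpus$layer == "entities" & rep$corpus$average == "micro", ]
  want <- expected_scores(p)
  want_ent <- want[want$layer == "entities", ]
  expect_lt(abs(ent$recall - want_ent$recall), 0.02)
  expect_lt(abs(ent$precision - want_ent$precision), 0.02)
  # attribute recall composes host survival with the drop rate
  p2 <- perturbation_config(p_delete = 0, p_attr_drop = 0.5, seed = 43)
  pert2 <- perturb_corpus(gold, p2)
  rep2 <- score_corpus(
    lapply(names(gold$documents), function(b) {
      list(reference = gold$documents[[b]], response = pert2[[b]])
    }),
    criteria = "strict"
  )
  at <- rep2$corpus[rep2$corpus$layer == "attributes" & rep2$corpus$average == "micro", ]
  expect_equal(at$precision, 1)
  expect_lt(abs(at$recall - 0.5), 0.05) # fewer attributes than entities
})

test_that("stratified systematic sampling selects every interval-th per stratum", {
  one <- stats::setNames(rep("low", 40), paste0("r", 1:40))
  expect_length(stratified_sample(one, interval = 10, seed = 1), 4L)

  four <- stats::setNames(
    rep(c("low", "moderate", "high", "unspecified"), each = 10),
    paste0("r", 1:40)
  )
  picked <- stratified_sample(four, interval = 10, seed = 1)
  expect_length(picked, 4L)
  expect_setequal(unname(four[picked]), c("low", "moderate", "high", "unspecified"))

  expect_identical(stratified_sample(character(), 10, 1), character())
  # deterministic under a fixed seed
  expect_identical(
    stratified_sample(four, 10, seed = 5), stratified_sample(four, 10, seed = 5)
  )

  # register-sized input: the selected count is the per-stratum floor sum
  set.seed(77)
  levels <- sample(c("low", "moderate", "high", "unspecified"), 1373,
    replace = TRUE, prob = c(0.45, 0.3, 0.05, 0.2)
  )
  reg <- stats::setNames(levels, sprintf("inc%04d", 1:1373))
  picked <- stratified_sample(reg, interval = 10, seed = 2)
  expect_length(picked, sum(table(levels) %/% 10))
})

test_that("a corpus object can be subsampled directly", {
  corpus <- generate_corpus(generator_config(seed = 51, n_reports = 25))
  sub <- stratified_sample(corpus, interval = 5, seed = 52)
  expect_s3_class(sub, "mrira_synthetic_corpus")
  expect_named(sub$documents, names(sub$harm_level))
  expect_lte(length(sub$documents), 5L)
})
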