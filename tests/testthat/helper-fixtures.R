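# Shared fixtures: the bundled worked-example document, tiny hand-rolled
# documents, and random instance generators for property tests.

example_corpus_dir <- function() {
  system.file("extdata", "example-corpus", package = "mrira", mustWork = TRUE)
}

example_doc <- function() {
  read_corpus(example_corpus_dir())[[1]]
}

# a one-sentence document whose annotations are easy to enumerate by hand:
# four word entities, one event, one relation, one attribute
tiny_doc <- function(ann_lines, text = "aa bb cc dd ee", doc_id = "tiny") {
  parse_document(text, paste(ann_lines, collapse = "\n"), doc_id)
}

withr_like_tempdir <- function() {
  d <- tempfile("mrira-test-")
  dir.create(d)
  d
}

# random alignment instance: typed single-fragment spans over a 60-char text,
# small enough for the brute-force oracle
random_alignment_instance <- function(max_side = 5L) {
  mk <- function(n, prefix) {
    recs <- lapply(seq_len(n), function(i) {
      start <- sample.int(54L, 1L) - 1L
      len <- sample.int(6L, 1L)
      new_entity_record(sample(c("A", "B"), 1L), span(start, start + len))
    })
    if (n) names(recs) <- paste0(prefix, seq_len(n))
    recs
  }
  list(
    reference = mk(sample.int(max_side + 1L, 1L) - 1L, "R"),
    response = mk(sample.int(max_side + 1L, 1L) - 1L, "S")
  )
}

# gold corpus plus an all-operator perturbed counterpart, as document pairs
random_scored_pairs <- function(n_reports, gen_seed, perturb_seed,
                                p = perturbation_config(
                                  p_delete = 0.10, p_insert = 0.10,
                                  p_boundary = 0.30, p_relabel = 0.10,
                                  p_attr_drop = 0.30, p_rel_retarget = 0.20,
                                  seed = perturb_seed
                                )) {
  gold <- generate_corpus(generator_config(seed = gen_seed, n_reports = n_reports))
  pert <- perturb_corpus(gold, p)
  lapply(names(gold$documents), function(b) {
    list(reference = gold$documents[[b]], response = pert[[b]])
  })
}
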