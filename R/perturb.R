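#' Configuration of the simulated-annotator disagreement model
#'
#' A second annotator is simulated by perturbing a gold document with
#' independent operators, each applied per annotation with its configured
#' rate. The operators mirror the disagreement patterns seen between real
#' annotators:
#'
#' * `p_boundary` — span-granularity disagreement: a boundary is jittered by
#'   a few characters while always preserving at least one character of
#'   overlap and the label (e.g. "morphine sulfate" vs "morphine").
#' * `p_attr_drop` — attribute-assignment disagreement: an attribute present
#'   for one annotator is left unset by the other.
#' * `p_rel_retarget` — relation-scope disagreement: a relation endpoint is
#'   moved to a different entity of a compatible type, when one exists.
#' * `p_relabel` — a type is swapped within a confusability set of
#'   commonly confused labels.
#' * `p_delete` / `p_insert` — plain recall/precision noise: an annotation is
#'   dropped, or a spurious one is added (expected `p_insert` spurious
#'   entities per gold entity, placed over unannotated words so they never
#'   coincide with gold).
#'
#' @param p_delete,p_insert,p_boundary,p_relabel,p_attr_drop,p_rel_retarget
#'   Rates in `[0, 1]` (see above); all default to 0.
#' @param seed Optional integer seed; when set, [perturb_document()] is
#'   deterministic on its own.
#' @param confusability Named list of character vectors: confusable label
#'   sets for `p_relabel` (entity and event types may be mixed across list
#'   entries, but each set must be all-entity or all-event).
#' @return A `perturbation_config` list, validated.
#' @export
perturbation_config <- function(p_delete = 0, p_insert = 0, p_boundary = 0,
                                p_relabel = 0, p_attr_drop = 0,
                                p_rel_retarget = 0, seed = NULL,
                                confusability = default_confusability()) {
  rates <- c(
    p_delete = p_delete, p_insert = p_insert, p_boundary = p_boundary,
    p_relabel = p_relabel, p_attr_drop = p_attr_drop,
    p_rel_retarget = p_rel_retarget
  )
  if (any(rates < 0 | rates > 1)) {
    stop("perturbation_config: all rates must lie in [0, 1]")
  }
  structure(
    c(as.list(rates), list(
      seed = if (is.null(seed)) NULL else as.integer(seed),
      confusability = confusability
    )),
    class = "perturbation_config"
  )
}

#' Default confusability sets for the relabel operator
#'
#' Pairs of labels that annotators plausibly confuse: quantity-like drug
#' attributes, abstract-object types, and the corrective/preventive action
#' distinction.
#'
#' @return Named list of character vectors.
#' @export
default_confusability <- function() {
  list(
    quantity = c("Drug dose", "Drug strength or amount"),
    abstract = c("Artefact", "Knowledge"),
    action = c("Corrective action", "Preventive action")
  )
}

relabel_within <- function(type, sets) {
  for (s in sets) {
    if (type %in% s && length(s) > 1L) {
      return(pick(setdiff(s, type)))
    }
  }
  type
}

# jitter one boundary of the span's first or last fragment by 1-3 characters,
# guaranteeing (a) the span changes, (b) >= 1 character of overlap with the
# original remains, (c) offsets stay inside the text, (d) the span never
# grows across a line break (annotators do not reach into the next
# subsection)
jitter_span <- function(sp, text) {
  text_len <- nchar(text)
  moves <- list()
  last <- nrow(sp)
  s1 <- sp[1L, 1L]
  e_last <- sp[last, 2L]
  room_right <- next_break_distance(text, e_last, forward = TRUE)
  room_left <- next_break_distance(text, s1, forward = FALSE)
  if (room_right > 0L) {
    moves[[length(moves) + 1L]] <- c("extend_end", min(3L, room_right))
  }
  if (sp[last, 2L] - sp[last, 1L] >= 2L) {
    moves[[length(moves) + 1L]] <- c("shrink_end", min(3L, sp[last, 2L] - sp[last, 1L] - 1L))
  }
  if (room_left > 0L) {
    moves[[length(moves) + 1L]] <- c("extend_start", min(3L, room_left))
  }
  if (sp[1L, 2L] - sp[1L, 1L] >= 2L) {
    moves[[length(moves) + 1L]] <- c("shrink_start", min(3L, sp[1L, 2L] - sp[1L, 1L] - 1L))
  }
  if (!length(moves)) {
    return(sp)
  }
  mv <- moves[[sample.int(length(moves), 1L)]]
  k <- sample.int(as.integer(mv[[2]]), 1L)
  out <- sp
  switch(mv[[1]],
    extend_end = out[last, 2L] <- out[last, 2L] + k,
    shrink_end = out[last, 2L] <- out[last, 2L] - k,
    extend_start = out[1L, 1L] <- out[1L, 1L] - k,
    shrink_start = out[1L, 1L] <- out[1L, 1L] + k
  )
  # jitter never merges fragments: starts stay sorted because only the outer
  # boundaries move and shrinks keep >= 1 character
  structure(out, class = class(sp))
}

# characters available before hitting a line break (or the text edge) when
# moving outward from offset `pos`
next_break_distance <- function(text, pos, forward) {
  if (forward) {
    rest <- substr(text, pos + 1L, nchar(text))
    hit <- regexpr("[\n\r]", rest)
    if (hit < 0L) nchar(rest) else hit - 1L
  } else {
    before <- substr(text, 1L, pos)
    hit <- regexpr("[\n\r][^\n\r]*$", before)
    if (hit < 0L) pos else pos - hit
  }
}

#' Simulate a second annotator
#'
#' Applies the disagreement operators of a [perturbation_config()] to a gold
#' document, returning a schema-valid document representing a plausible
#' independent annotator. Deleting an annotation cascades: relations lose
#' deleted endpoints, events lose deleted argument fillers, attributes of
#' deleted events disappear — the output never dangles. Relabelling an
#' entity drops any relation whose endpoint constraint it would break.
#'
#' @param gold A schema-valid [mrira_document()].
#' @param p A [perturbation_config()].
#' @param schema Schema used for endpoint compatibility of insertions,
#'   retargets and relabel cascades.
#' @return A perturbed [mrira_document()] with the same text.
#' @export
perturb_document <- function(gold, p, schema = default_schema()) {
  stopifnot(inherits(p, "perturbation_config"))
  with_seed(p$seed, perturb_document_impl(gold, p, schema))
}

perturb_document_impl <- function(gold, p, schema) {
  doc <- gold
  trig <- trigger_ids(doc)

  # 1) relabel (entities within confusability sets; events retype their
  #    trigger too)
  if (p$p_relabel > 0) {
    for (id in setdiff(names(doc$entities), trig)) {
      if (bern(p$p_relabel)) {
        doc$entities[[id]]$type <- relabel_within(
          doc$entities[[id]]$type, p$confusability
        )
      }
    }
    for (id in names(doc$events)) {
      if (bern(p$p_relabel)) {
        new_type <- relabel_within(doc$events[[id]]$type, p$confusability)
        doc$events[[id]]$type <- new_type
        doc$entities[[doc$events[[id]]$trigger]]$type <- new_type
      }
    }
    # drop relations whose endpoint constraint the relabel broke
    keep <- vapply(doc$relations, function(rel) {
      allowed <- schema$relations[schema$relations$name == rel$type, ]
      st <- doc$entities[[rel$source]]$type
      tt <- doc$entities[[rel$target]]$type
      any(allowed$source == st & allowed$target == tt)
    }, logical(1))
    doc$relations <- doc$relations[keep]
  }

  # 2) boundary jitter on all text-bound annotations (triggers included)
  if (p$p_boundary > 0) {
    for (id in names(doc$entities)) {
      if (bern(p$p_boundary)) {
        sp <- jitter_span(doc$entities[[id]]$span, doc$text)
        doc$entities[[id]]$span <- sp
        doc$entities[[id]]$surface <- span_surface(sp, doc$text)
      }
    }
  }

  # 3) deletion with cascade
  if (p$p_delete > 0) {
    del_ent <- names(doc$entities)[
      !names(doc$entities) %in% trig &
        stats::runif(length(doc$entities)) < p$p_delete
    ]
    del_evt <- names(doc$events)[stats::runif(length(doc$events)) < p$p_delete]
    del_rel <- names(doc$relations)[stats::runif(length(doc$relations)) < p$p_delete]
    # events die with their triggers; their attributes die with them
    del_trig <- vapply(
      doc$events[del_evt], function(ev) ev$trigger, character(1)
    )
    gone_ent <- c(del_ent, unname(del_trig))
    doc$entities <- doc$entities[!names(doc$entities) %in% gone_ent]
    doc$events <- doc$events[!names(doc$events) %in% del_evt]
    doc$relations <- doc$relations[!names(doc$relations) %in% del_rel]
    # cascade: drop relations touching deleted entities, arguments whose
    # filler vanished, attributes whose host vanished
    doc$relations <- Filter(function(rel) {
      rel$source %in% names(doc$entities) && rel$target %in% names(doc$entities)
    }, doc$relations)
    alive <- c(names(doc$entities), names(doc$events))
    doc$events <- lapply(doc$events, function(ev) {
      ev$args <- Filter(function(a) a$filler %in% alive, ev$args)
      ev
    })
    doc$attributes <- Filter(function(at) at$host %in% alive, doc$attributes)
  }

  # 4) attribute drop
  if (p$p_attr_drop > 0) {
    doc$attributes <- doc$attributes[
      stats::runif(length(doc$attributes)) >= p$p_attr_drop
    ]
  }

  # 5) relation retarget: move the target to another compatible entity
  if (p$p_rel_retarget > 0) {
    for (id in names(doc$relations)) {
      if (!bern(p$p_rel_retarget)) next
      rel <- doc$relations[[id]]
      allowed <- schema$relations[schema$relations$name == rel$type, ]
      tt <- allowed$target[allowed$source == doc$entities[[rel$source]]$type]
      cand <- names(Filter(function(e) e$type %in% tt, doc$entities))
      cand <- setdiff(cand, rel$target)
      if (length(cand)) doc$relations[[id]]$target <- pick(cand)
    }
  }

  # 6) spurious entity insertions over unannotated words
  if (p$p_insert > 0) {
    n_gold_ent <- length(gold$entities) - length(trigger_ids(gold))
    n_ins <- stats::rbinom(1L, n_gold_ent, p$p_insert)
    if (n_ins > 0L) {
      free <- free_word_spans(gold)
      if (nrow(free)) {
        take <- free[sample.int(nrow(free), min(n_ins, nrow(free))), , drop = FALSE]
        ent_types <- schema$entity_types$name
        next_t <- max(c(0L, as.integer(sub("^T", "", names(doc$entities))))) + 1L
        for (k in seq_len(nrow(take))) {
          id <- paste0("T", next_t)
          next_t <- next_t + 1L
          sp <- span(take[k, 1L], take[k, 2L])
          doc$entities[[id]] <- new_entity(
            id, pick(ent_types), sp, span_surface(sp, doc$text)
          )
        }
      }
    }
  }

  mrira_document(
    doc_id = doc$doc_id, text = doc$text,
    entities = doc$entities, events = doc$events,
    relations = doc$relations, attributes = doc$attributes,
    notes = doc$notes
  )
}

# word spans of the text that do not overlap any gold annotation span
free_word_spans <- function(doc) {
  m <- gregexpr("[^[:space:]]+", doc$text)[[1]]
  if (m[[1]] == -1L) {
    return(cbind(start = integer(), end = integer()))
  }
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  occupied <- do.call(rbind, lapply(doc$entities, function(e) unclass(e$span)))
  keep <- vapply(seq_along(starts), function(i) {
    if (is.null(occupied)) {
      return(TRUE)
    }
    !any(pmax(starts[[i]], occupied[, 1L]) < pmin(ends[[i]], occupied[, 2L]))
  }, logical(1))
  cbind(start = starts[keep], end = ends[keep])
}

#' Perturb a whole corpus
#'
#' Applies [perturb_document()] to every document of a synthetic corpus (or
#' plain document list) under a single seed, so the corpus-level result is
#' reproducible.
#'
#' @param corpus An `mrira_synthetic_corpus` or named list of documents.
#' @param p A [perturbation_config()]; its `seed` governs the whole run.
#' @param schema Schema for schema-aware operators.
#' @return A named list of perturbed documents.
#' @export
perturb_corpus <- function(corpus, p, schema = default_schema()) {
  docs <- if (inherits(corpus, "mrira_synthetic_corpus")) corpus$documents else corpus
  with_seed(
    p$seed,
    lapply(docs, perturb_document_impl, p = p, schema = schema)
  )
}

#' Closed-form expected agreement under deletion/insertion noise
#'
#' For the pure recall/precision noise model (deletion and insertion only —
#' no boundary, relabel or retarget noise, for which no closed form is
#' claimed), the expected corpus micro scores follow directly from the
#' operator definitions. With deletion rate `d` and insertion rate `i`:
#' entity recall is `1 - d` and precision `(1 - d) / (1 - d + i)`; events and
#' relations see only deletions (recall `1 - d` and `(1 - d)^3`
#' respectively, the relation requiring its own survival and both
#' endpoints'); an attribute survives with its host event and its own drop
#' rate, recall `(1 - d) * (1 - a)`. Precision is 1 on layers where nothing
#' spurious is inserted.
#'
#' @param p A [perturbation_config()] with
#'   `p_boundary = p_relabel = p_rel_retarget = 0` (otherwise the function
#'   refuses).
#' @return Tibble with columns `layer`, `precision`, `recall`, `f1`.
#' @examples
#' expected_scores(perturbation_config(p_delete = 0.2)) # entity F1 = 8/9
#' @export
expected_scores <- function(p) {
  stopifnot(inherits(p, "perturbation_config"))
  if (p$p_boundary > 0 || p$p_relabel > 0 || p$p_rel_retarget > 0) {
    stop(paste(
      "expected_scores: closed form is only valid for the deletion/insertion",
      "model (p_boundary = p_relabel = p_rel_retarget = 0)"
    ))
  }
  d <- p$p_delete
  i <- p$p_insert
  a <- p$p_attr_drop
  f1 <- function(pr, rc) if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  ent_p <- if ((1 - d) + i == 0) 1 else (1 - d) / ((1 - d) + i)
  rows <- list(
    c("entities", ent_p, 1 - d),
    c("relations", 1, (1 - d)^3),
    c("events", 1, 1 - d),
    c("attributes", 1, (1 - d) * (1 - a))
  )
  do.call(rbind, lapply(rows, function(r) {
    pr <- as.numeric(r[[2]])
    rc <- as.numeric(r[[3]])
    tibble::tibble(layer = r[[1]], precision = pr, recall = rc, f1 = f1(pr, rc))
  }))
}

#' Stratified systematic sample of reports
#'
#' Partitions reports by harm level and, within each stratum (after a seeded
#' shuffle fixing the listing order), selects every `interval`-th report —
#' the "one in every ten listed" design used to draw screening pools from
#' incident registers.
#'
#' @param reports A named character vector of harm levels (names are report
#'   ids), or an `mrira_synthetic_corpus`.
#' @param interval Positive integer sampling interval.
#' @param seed Integer seed for the within-stratum shuffle.
#' @return For a harm-level vector: the selected report ids (character). For
#'   a corpus: the sub-corpus of selected reports.
#' @export
stratified_sample <- function(reports, interval = 10L, seed = 1L) {
  stopifnot(interval >= 1)
  if (inherits(reports, "mrira_synthetic_corpus")) {
    ids <- stratified_sample(reports$harm_level, interval, seed)
    return(structure(
      list(
        documents = reports$documents[ids],
        harm_level = reports$harm_level[ids]
      ),
      class = "mrira_synthetic_corpus"
    ))
  }
  if (!length(reports)) {
    return(character())
  }
  stopifnot(!is.null(names(reports)))
  with_seed(seed, {
    selected <- character()
    for (lev in unique(reports)) {
      ids <- names(reports)[reports == lev]
      ids <- ids[sample.int(length(ids))]
      take <- seq_len(length(ids) %/% interval) * interval
      selected <- c(selected, ids[take])
    }
    selected
  })
}
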