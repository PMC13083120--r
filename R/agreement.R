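#' Precision, recall and F1 from match counts
#'
#' Precision is the proportion of the response annotator's annotations that
#' match the reference; recall is the proportion of the reference annotator's
#' annotations found by the response; F1 is their harmonic mean. An empty
#' side scores 1 by convention (nothing to find, nothing found wrongly):
#' this matters only at the document level, since corpus micro scores pool
#' raw counts and the convention never inflates them.
#'
#' @param matched Number of one-to-one matched pairs.
#' @param n_reference,n_response Annotation counts on each side.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @examples
#' compute_prf(3, 4, 4) # 0.75 across the board
#' compute_prf(1, 1, 2) # precision 0.5, recall 1, F1 2/3
#' @export
compute_prf <- function(matched, n_reference, n_response) {
  stopifnot(matched >= 0, n_reference >= 0, n_response >= 0)
  if (matched > min(n_reference, n_response)) {
    stop("compute_prf: matched count exceeds an annotation count")
  }
  p <- if (n_response == 0) 1 else matched / n_response
  r <- if (n_reference == 0) 1 else matched / n_reference
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

agreement_layers <- c("entities", "relations", "events", "attributes")

# records suitable for span_match, one per event (the trigger's span with the
# event's type)
event_trigger_records <- function(doc) {
  lapply(doc$events, function(ev) {
    trig <- doc$entities[[ev$trigger]]
    list(id = ev$id, type = ev$type, span = trig$span)
  })
}

non_trigger_entities <- function(doc) {
  doc$entities[setdiff(names(doc$entities), trigger_ids(doc))]
}

pair_lookup <- function(corr) {
  stats::setNames(corr$pairs$response, corr$pairs$reference)
}

# match counts for all four layers of one document pair under one criterion.
# The entity correspondence is computed once and reused by the relations
# layer; the event correspondence is reused by the attributes layer.
layer_counts <- function(reference, response, criterion, schema = NULL) {
  if (!identical(reference$text, response$text)) {
    stop(sprintf(
      "documents '%s' and '%s' have different texts; annotations are not comparable",
      reference$doc_id, response$doc_id
    ))
  }
  if (!is.null(schema)) {
    reference <- resolve_document(reference, schema)
    response <- resolve_document(response, schema)
  }

  ref_ent <- non_trigger_entities(reference)
  res_ent <- non_trigger_entities(response)
  ent_corr <- align_annotations(ref_ent, res_ent, criterion)
  ent_map <- pair_lookup(ent_corr)

  ref_evt <- event_trigger_records(reference)
  res_evt <- event_trigger_records(response)
  evt_corr <- align_annotations(ref_evt, res_evt, criterion)
  evt_map <- pair_lookup(evt_corr)

  rel_match <- function(a, b) {
    identical(a$type, b$type) &&
      identical(unname(ent_map[a$source]), b$source) &&
      identical(unname(ent_map[a$target]), b$target)
  }
  rel_corr <- align_annotations(
    reference$relations, response$relations,
    match_fun = rel_match
  )

  attr_match <- function(a, b) {
    identical(a$name, b$name) &&
      identical(a$value, b$value) &&
      identical(unname(evt_map[a$host]), b$host)
  }
  attr_corr <- align_annotations(
    reference$attributes, response$attributes,
    match_fun = attr_match
  )

  list(
    entities = c(
      matched = nrow(ent_corr$pairs),
      n_reference = length(ref_ent), n_response = length(res_ent)
    ),
    relations = c(
      matched = nrow(rel_corr$pairs),
      n_reference = length(reference$relations),
      n_response = length(response$relations)
    ),
    events = c(
      matched = nrow(evt_corr$pairs),
      n_reference = length(reference$events),
      n_response = length(response$events)
    ),
    attributes = c(
      matched = nrow(attr_corr$pairs),
      n_reference = length(reference$attributes),
      n_response = length(response$attributes)
    )
  )
}

#' Score one annotation layer of a document pair
#'
#' Computes inter-annotator agreement for one layer of two independently
#' annotated copies of the same narrative, under one matching criterion:
#'
#' * `entities` — typed spans, excluding event triggers (those are scored
#'   with their events);
#' * `events` — trigger spans matched under the criterion, with equal event
#'   types;
#' * `relations` — equal relation types with both endpoints paired in the
#'   entity correspondence computed under the same criterion;
#' * `attributes` — equal attribute names (and values, when valued) with host
#'   events paired in the event correspondence.
#'
#' @param reference,response [mrira_document()]s over identical text.
#' @param layer One of `"entities"`, `"relations"`, `"events"`,
#'   `"attributes"`.
#' @param criterion `"strict"` or `"relaxed"`.
#' @param schema Schema used for alias resolution (default: the bundled
#'   scheme); pass `NULL` if labels are already canonical.
#' @return A one-row tibble: `layer`, `criterion`, `matched`, `n_reference`,
#'   `n_response`, `precision`, `recall`, `f1`.
#' @export
score_layer <- function(reference, response,
                        layer = agreement_layers,
                        criterion = c("strict", "relaxed"),
                        schema = default_schema()) {
  layer <- match.arg(layer)
  criterion <- match.arg(criterion)
  counts <- layer_counts(reference, response, criterion, schema)[[layer]]
  prf <- compute_prf(counts[["matched"]], counts[["n_reference"]], counts[["n_response"]])
  tibble::tibble(
    layer = layer, criterion = criterion,
    matched = counts[["matched"]],
    n_reference = counts[["n_reference"]],
    n_response = counts[["n_response"]],
    precision = prf[["precision"]], recall = prf[["recall"]], f1 = prf[["f1"]]
  )
}

#' Score a corpus of document pairs
#'
#' Computes agreement for every layer and criterion across a corpus,
#' reporting both micro averages (counts pooled over documents, the headline
#' figure) and macro averages (unweighted mean of per-document scores;
#' documents where a layer is empty on both sides are excluded from that
#' layer's macro mean). An interpretation band is attached to every F1 (see
#' [classify_band()]).
#'
#' @param pairs List of `list(reference = , response = )` document pairs (or
#'   a two-element list of equal-length document lists).
#' @param criteria Character vector of criteria to evaluate.
#' @param schema Schema for alias resolution.
#' @return An `mrira_agreement_report`: `per_document` (tibble of
#'   document-level scores) and `corpus` (tibble of micro and macro rows per
#'   layer and criterion, with band labels). Layers empty on both sides in
#'   every document get `NA` scores, not 0.
#' @export
score_corpus <- function(pairs, criteria = c("strict", "relaxed"),
                         schema = default_schema()) {
  if (!length(pairs)) stop("score_corpus: no document pairs supplied")
  criteria <- match.arg(criteria, c("strict", "relaxed"), several.ok = TRUE)

  per_doc <- list()
  for (crit in criteria) {
    for (k in seq_along(pairs)) {
      pr <- pairs[[k]]
      counts <- layer_counts(pr$reference, pr$response, crit, schema)
      for (layer in agreement_layers) {
        ct <- counts[[layer]]
        prf <- compute_prf(ct[["matched"]], ct[["n_reference"]], ct[["n_response"]])
        per_doc[[length(per_doc) + 1L]] <- tibble::tibble(
          doc_id = pr$reference$doc_id, layer = layer, criterion = crit,
          matched = ct[["matched"]], n_reference = ct[["n_reference"]],
          n_response = ct[["n_response"]],
          precision = prf[["precision"]], recall = prf[["recall"]],
          f1 = prf[["f1"]]
        )
      }
    }
  }
  per_doc <- do.call(rbind, per_doc)

  corpus <- list()
  for (crit in criteria) {
    for (layer in agreement_layers) {
      rows <- per_doc[per_doc$layer == layer & per_doc$criterion == crit, ]
      tot <- c(
        matched = sum(rows$matched),
        n_reference = sum(rows$n_reference),
        n_response = sum(rows$n_response)
      )
      layer_empty <- tot[["n_reference"]] == 0 && tot[["n_response"]] == 0
      if (layer_empty) {
        micro <- c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
        macro <- micro
      } else {
        micro <- compute_prf(
          tot[["matched"]], tot[["n_reference"]], tot[["n_response"]]
        )
        keep <- rows$n_reference > 0 | rows$n_response > 0
        macro <- c(
          precision = mean(rows$precision[keep]),
          recall = mean(rows$recall[keep]),
          f1 = mean(rows$f1[keep])
        )
      }
      for (avg in c("micro", "macro")) {
        sc <- if (avg == "micro") micro else macro
        bd <- classify_band(sc[["f1"]], layer)
        corpus[[length(corpus) + 1L]] <- tibble::tibble(
          layer = layer, criterion = crit, average = avg,
          matched = tot[["matched"]], n_reference = tot[["n_reference"]],
          n_response = tot[["n_response"]],
          precision = sc[["precision"]], recall = sc[["recall"]],
          f1 = sc[["f1"]],
          band = bd$band,
          potentially_acceptable = bd$potentially_acceptable
        )
      }
    }
  }
  structure(
    list(per_document = per_doc, corpus = do.call(rbind, corpus)),
    class = "mrira_agreement_report"
  )
}

#' @export
print.mrira_agreement_report <- function(x, ...) {
  cat("Inter-annotator agreement (corpus level)\n")
  print(x$corpus, n = nrow(x$corpus))
  invisible(x)
}

#' Interpretation band for an F1 score
#'
#' Span-annotation F1 is conventionally read as high above 0.80, moderate
#' from 0.60 to 0.80, and low below 0.60. Event-like layers (events,
#' attributes) routinely score lower; there, values between 0.50 and 0.60
#' are additionally flagged as potentially acceptable.
#'
#' @param f1 F1 score in `[0, 1]` (`NA` allowed for undefined layers).
#' @param layer Layer name; the potentially-acceptable flag applies to
#'   `"events"` and `"attributes"`.
#' @return `list(band = "high"|"moderate"|"low"|NA, potentially_acceptable =
#'   logical)`.
#' @examples
#' classify_band(0.85, "entities") # high
#' classify_band(0.62, "events") # moderate
#' classify_band(0.51, "attributes") # low, potentially acceptable
#' @export
classify_band <- function(f1, layer = agreement_layers) {
  layer <- match.arg(layer)
  if (is.na(f1)) {
    return(list(band = NA_character_, potentially_acceptable = NA))
  }
  if (f1 < 0 || f1 > 1) stop("classify_band: f1 must lie in [0, 1]")
  band <- if (f1 > 0.80) "high" else if (f1 >= 0.60) "moderate" else "low"
  flag <- layer %in% c("events", "attributes") && f1 >= 0.50 && f1 <= 0.60
  list(band = band, potentially_acceptable = flag)
}

#' Diagnostic: agreement on event arguments
#'
#' Role-labelled argument links are not part of the event layer score (which
#' uses trigger and type only); this diagnostic scores them separately. An
#' argument matches when its event is paired in the event correspondence,
#' the role is equal, and the fillers are paired in the entity (or event)
#' correspondence under the same criterion.
#'
#' @inheritParams score_layer
#' @return A one-row tibble like [score_layer()], with `layer = "arguments"`.
#' @export
score_event_arguments <- function(reference, response,
                                  criterion = c("strict", "relaxed"),
                                  schema = default_schema()) {
  criterion <- match.arg(criterion)
  if (!identical(reference$text, response$text)) {
    stop("documents have different texts; annotations are not comparable")
  }
  if (!is.null(schema)) {
    reference <- resolve_document(reference, schema)
    response <- resolve_document(response, schema)
  }
  ent_corr <- align_annotations(
    non_trigger_entities(reference), non_trigger_entities(response), criterion
  )
  evt_corr <- align_annotations(
    event_trigger_records(reference), event_trigger_records(response), criterion
  )
  fill_map <- c(pair_lookup(ent_corr), pair_lookup(evt_corr))
  evt_map <- pair_lookup(evt_corr)

  arg_records <- function(doc) {
    out <- list()
    for (ev in doc$events) {
      for (a in ev$args) {
        out[[length(out) + 1L]] <- list(event = ev$id, role = a$role, filler = a$filler)
      }
    }
    out
  }
  ref_args <- arg_records(reference)
  res_args <- arg_records(response)
  arg_match <- function(a, b) {
    identical(unname(evt_map[a$event]), b$event) &&
      identical(a$role, b$role) &&
      identical(unname(fill_map[a$filler]), b$filler)
  }
  corr <- align_annotations(ref_args, res_args, match_fun = arg_match)
  prf <- compute_prf(nrow(corr$pairs), length(ref_args), length(res_args))
  tibble::tibble(
    layer = "arguments", criterion = criterion,
    matched = nrow(corr$pairs), n_reference = length(ref_args),
    n_response = length(res_args),
    precision = prf[["precision"]], recall = prf[["recall"]], f1 = prf[["f1"]]
  )
}
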