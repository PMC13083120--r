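#' Annotated documents
#'
#' An `mrira_document` bundles one narrative's text with all of its standoff
#' annotations. It is the unit of input/output, validation and scoring.
#'
#' Annotations live in four collections, each a named list keyed by
#' annotation identifier:
#'
#' * `entities` — text-bound annotations (`T` identifiers): typed spans with
#'   their covered surface text. Event triggers are stored here too, as the
#'   standoff dialect does; scoring distinguishes them (see
#'   [score_layer()]).
#' * `events` — `E` identifiers: an event type, a reference to the trigger
#'   entity, and zero or more role-labelled arguments.
#' * `relations` — `R` identifiers: a typed, directed link between two
#'   entities.
#' * `attributes` — `A` identifiers: a named modifier on an event, optionally
#'   carrying a value token (absent means a binary flag that is present).
#'
#' `notes` holds `#`-prefixed annotator-note lines verbatim; they round-trip
#' through serialization and are ignored by validation and scoring.
#'
#' @param doc_id Document name (usually the file basename).
#' @param text Full narrative text.
#' @param entities,events,relations,attributes Named lists of annotation
#'   records (see Details); usually produced by [parse_document()] or
#'   [generate_corpus()], not by hand.
#' @param notes Character vector of raw note lines.
#' @return An object of class `mrira_document`.
#' @seealso [parse_document()], [serialize_document()], [validate_document()]
#' @export
mrira_document <- function(doc_id, text, entities = list(), events = list(),
                           relations = list(), attributes = list(),
                           notes = character()) {
  doc <- structure(
    list(
      doc_id = doc_id, text = text,
      entities = entities, events = events,
      relations = relations, attributes = attributes,
      notes = notes
    ),
    class = "mrira_document"
  )
  check_document_integrity(doc)
  doc
}

new_entity <- function(id, type, sp, surface) {
  list(id = id, type = type, span = sp, surface = surface)
}

new_event <- function(id, type, trigger, args = list()) {
  # args: list of list(role = , filler = )
  list(id = id, type = type, trigger = trigger, args = args)
}

new_relation <- function(id, type, source, target) {
  list(id = id, type = type, source = source, target = target)
}

new_attribute <- function(id, name, host, value = NULL) {
  list(id = id, name = name, host = host, value = value)
}

ann_ids <- function(doc) {
  c(
    names(doc$entities), names(doc$events),
    names(doc$relations), names(doc$attributes)
  )
}

# structural invariants: unique identifiers, no dangling references,
# offsets within text, stored surface matches the text
check_document_integrity <- function(doc) {
  ids <- ann_ids(doc)
  if (anyDuplicated(ids)) {
    stop(sprintf(
      "document '%s': duplicate annotation identifier(s): %s",
      doc$doc_id, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ), call. = FALSE)
  }
  n_text <- nchar(doc$text)
  for (ent in doc$entities) {
    validate_span(ent$span, n_text, where = sprintf("entity %s", ent$id))
    got <- span_surface(ent$span, doc$text)
    if (!identical(got, ent$surface)) {
      stop(sprintf(
        "document '%s': entity %s surface mismatch: stored '%s', text has '%s'",
        doc$doc_id, ent$id, ent$surface, got
      ), call. = FALSE)
    }
  }
  known <- c(names(doc$entities), names(doc$events))
  for (ev in doc$events) {
    if (!ev$trigger %in% names(doc$entities)) {
      stop(sprintf(
        "document '%s': event %s references missing trigger %s",
        doc$doc_id, ev$id, ev$trigger
      ), call. = FALSE)
    }
    for (a in ev$args) {
      if (!a$filler %in% known) {
        stop(sprintf(
          "document '%s': event %s argument %s references missing %s",
          doc$doc_id, ev$id, a$role, a$filler
        ), call. = FALSE)
      }
    }
  }
  for (rel in doc$relations) {
    for (endp in c(rel$source, rel$target)) {
      if (!endp %in% known) {
        stop(sprintf(
          "document '%s': relation %s references missing annotation %s",
          doc$doc_id, rel$id, endp
        ), call. = FALSE)
      }
    }
  }
  for (at in doc$attributes) {
    if (!at$host %in% known) {
      stop(sprintf(
        "document '%s': attribute %s references missing annotation %s",
        doc$doc_id, at$id, at$host
      ), call. = FALSE)
    }
  }
  invisible(doc)
}

# identifiers of entities that anchor an event (its trigger)
trigger_ids <- function(doc) {
  unique(vapply(doc$events, function(ev) ev$trigger, character(1)))
}

#' @export
print.mrira_document <- function(x, ...) {
  cat(sprintf(
    "<mrira_document '%s': %d chars, %d entities, %d events, %d relations, %d attributes>\n",
    x$doc_id, nchar(x$text), length(x$entities), length(x$events),
    length(x$relations), length(x$attributes)
  ))
  invisible(x)
}

#' Tabulate a document's entity mentions
#'
#' Convenience accessor used by corpus statistics and reporting: one row per
#' text-bound annotation with its type, offsets and surface form.
#'
#' @param doc An `mrira_document`.
#' @return A tibble with columns `id`, `type`, `start`, `end` (offsets of the
#'   first/last fragment), `n_fragments`, `surface`, and `is_trigger`.
#' @export
entity_table <- function(doc) {
  trig <- trigger_ids(doc)
  rows <- lapply(doc$entities, function(ent) {
    tibble::tibble(
      id = ent$id, type = ent$type,
      start = ent$span[1L, 1L], end = ent$span[nrow(ent$span), 2L],
      n_fragments = nrow(ent$span), surface = ent$surface,
      is_trigger = ent$id %in% trig
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(
      id = character(), type = character(), start = integer(),
      end = integer(), n_fragments = integer(), surface = character(),
      is_trigger = logical()
    ))
  }
  do.call(rbind, rows)
}
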