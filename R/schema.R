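#' The MRIRA annotation scheme
#'
#' The scheme is a declarative registry of the types an annotated
#' medication-incident narrative may use: 16 entity types (6 general, 2
#' patient-specific, 8 domain-specific), 11 event types (5 main stages of the
#' medication-use process plus 6 supplementary event types), 5 event
#' attributes (four mutually exclusive intent/actuality labels plus
#' `Negated`), 6 event argument roles, and 9 directed entity-relation types
#' with 10 allowed (source-type, target-type) endpoint pairs — `has
#' frequency` may start from either `Drug name` or `Drug dose`.
#'
#' `default_schema()` loads the bundled registry. Variant spellings that
#' occur in practice (e.g. `Dosage form` for `Drug form`, `Patient age` for
#' `Age group`) are registered as aliases and resolved transparently by
#' [resolve_type_alias()]. An optional event-to-event `Mismatch` link can be
#' enabled for corpora that annotate discrepancies between stages (e.g.
#' prescribed oral, administered IV); it is off by default and is never
#' counted among the 9 entity relations.
#'
#' @return An object of class `mrira_schema`.
#' @seealso [read_schema()], [validate_document()], [resolve_type_alias()]
#' @examples
#' sch <- default_schema()
#' length(sch$entity_types$name) # 16
#' @export
default_schema <- function() {
  read_schema(system.file("extdata", "mrira-schema.yaml",
    package = "mrira", mustWork = TRUE
  ))
}

#' Read or write a schema configuration
#'
#' Schemas are plain YAML so that non-MRIRA annotation schemes can be plugged
#' into the same validation and agreement machinery.
#'
#' @param path YAML file path.
#' @param schema An `mrira_schema`.
#' @return `read_schema()` returns an `mrira_schema`; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c(
    "name", "entity_types", "event_types", "attribute_names",
    "argument_roles", "relations"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(sprintf(
      "schema '%s' lacks field(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
  ent <- tibble::tibble(
    name = unlist(raw$entity_types, use.names = FALSE),
    group = rep(names(raw$entity_types), lengths(raw$entity_types))
  )
  evt <- tibble::tibble(
    name = unlist(raw$event_types, use.names = FALSE),
    group = rep(names(raw$event_types), lengths(raw$event_types))
  )
  rel <- do.call(rbind, lapply(raw$relations, function(r) {
    tibble::tibble(name = r$name, source = r$source, target = r$target)
  }))
  if (any(!nzchar(rel$name)) || nrow(rel) < 1L) {
    stop("schema: every relation needs a name and at least one endpoint pair")
  }
  bad <- setdiff(c(rel$source, rel$target), ent$name)
  if (length(bad)) {
    stop(sprintf(
      "schema: relation endpoint type(s) not among entity types: %s",
      paste(unique(bad), collapse = ", ")
    ))
  }
  aliases <- unlist(raw$aliases %||% list())
  sch <- structure(
    list(
      name = raw$name,
      entity_types = ent,
      event_types = evt,
      attribute_names = unlist(raw$attribute_names),
      intent_attributes = unlist(raw$intent_attributes %||% list()),
      argument_roles = unlist(raw$argument_roles),
      relations = rel,
      mismatch_name = raw$mismatch_link$name %||% "Mismatch",
      mismatch_enabled = isTRUE(raw$mismatch_link$enabled),
      aliases = aliases
    ),
    class = "mrira_schema"
  )
  if (anyDuplicated(c(sch$entity_types$name, sch$event_types$name))) {
    stop("schema: entity and event type names must be distinct")
  }
  sch
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "mrira_schema"))
  out <- list(
    name = schema$name,
    entity_types = split(
      schema$entity_types$name,
      factor(schema$entity_types$group, unique(schema$entity_types$group))
    ),
    event_types = split(
      schema$event_types$name,
      factor(schema$event_types$group, unique(schema$event_types$group))
    ),
    attribute_names = as.list(schema$attribute_names),
    intent_attributes = as.list(schema$intent_attributes),
    argument_roles = as.list(schema$argument_roles),
    relations = lapply(seq_len(nrow(schema$relations)), function(i) {
      list(
        name = schema$relations$name[i],
        source = schema$relations$source[i],
        target = schema$relations$target[i]
      )
    }),
    mismatch_link = list(
      name = schema$mismatch_name, enabled = schema$mismatch_enabled
    ),
    aliases = as.list(schema$aliases)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.mrira_schema <- function(x, ...) {
  cat(sprintf(
    "<mrira_schema '%s': %d entity types, %d event types, %d attributes, %d relation types, %d roles>\n",
    x$name, nrow(x$entity_types), nrow(x$event_types),
    length(x$attribute_names), length(unique(x$relations$name)),
    length(x$argument_roles)
  ))
  invisible(x)
}

#' Scheme size summary
#'
#' Counts of distinct types per layer of a schema, in the order entity
#' types, event types, attribute types, relation types, argument roles.
#'
#' @param schema An `mrira_schema`.
#' @return Named integer vector.
#' @export
schema_counts <- function(schema) {
  c(
    entity_types = nrow(schema$entity_types),
    event_types = nrow(schema$event_types),
    attribute_types = length(schema$attribute_names),
    relation_types = length(unique(schema$relations$name)),
    argument_roles = length(schema$argument_roles)
  )
}

all_canonical <- function(schema) {
  c(
    schema$entity_types$name, schema$event_types$name,
    schema$attribute_names, schema$argument_roles,
    unique(schema$relations$name),
    if (schema$mismatch_enabled) schema$mismatch_name
  )
}

#' Resolve a type label to its canonical form
#'
#' Maps variant spellings (registered in the schema's alias table, or
#' differing only in underscore-for-space substitution) onto the canonical
#' type label. Unknown labels are returned unchanged, flagged as unknown —
#' classifying them as errors is the validator's job, not the resolver's.
#'
#' @param schema An `mrira_schema`.
#' @param label Character vector of labels.
#' @return A character vector of the same length with attribute `unknown`, a
#'   logical vector marking labels that resolved to nothing.
#' @examples
#' sch <- default_schema()
#' resolve_type_alias(sch, "Dosage form") # "Drug form"
#' @export
resolve_type_alias <- function(schema, label) {
  canon <- all_canonical(schema)
  out <- character(length(label))
  unknown <- logical(length(label))
  for (i in seq_along(label)) {
    cand <- c(label[[i]], gsub("_", " ", label[[i]], fixed = TRUE))
    hit <- NA_character_
    for (x in cand) {
      if (x %in% canon) {
        hit <- x
        break
      }
      if (x %in% names(schema$aliases)) {
        hit <- unname(schema$aliases[[x]])
        break
      }
    }
    if (is.na(hit)) {
      out[[i]] <- label[[i]]
      unknown[[i]] <- TRUE
    } else {
      out[[i]] <- hit
    }
  }
  attr(out, "unknown") <- unknown
  out
}

resolve1 <- function(schema, label) {
  r <- resolve_type_alias(schema, label)
  list(label = r[[1]], unknown = attr(r, "unknown")[[1]])
}

# names accepted as the valued intent/actuality attribute form, normalised to
# one of the four binary intent attributes by resolve_document()
intent_value_names <- c("Intent", "Intent and actuality", "Intent actuality")

#' Alias-resolve all labels in a document
#'
#' Rewrites every entity/event/relation/attribute/role label to its canonical
#' schema form, and normalises the valued intent/actuality attribute form
#' (`Intent <host> <label>`) into the equivalent binary attribute. Unknown
#' labels are left untouched for the validator to report.
#'
#' @param doc An [mrira_document()].
#' @param schema An `mrira_schema`.
#' @return The document with canonical labels.
#' @export
resolve_document <- function(doc, schema) {
  doc$entities <- lapply(doc$entities, function(ent) {
    ent$type <- resolve1(schema, ent$type)$label
    ent
  })
  doc$events <- lapply(doc$events, function(ev) {
    ev$type <- resolve1(schema, ev$type)$label
    ev$args <- lapply(ev$args, function(a) {
      a$role <- resolve1(schema, a$role)$label
      a
    })
    ev
  })
  doc$relations <- lapply(doc$relations, function(rel) {
    rel$type <- resolve1(schema, rel$type)$label
    rel
  })
  doc$attributes <- lapply(doc$attributes, function(at) {
    if (at$name %in% intent_value_names && !is.null(at$value)) {
      val <- resolve1(schema, at$value)
      if (!val$unknown && val$label %in% schema$intent_attributes) {
        at$name <- val$label
        at$value <- NULL
        return(at)
      }
    }
    at$name <- resolve1(schema, at$name)$label
    at
  })
  doc
}

violation_row <- function(doc_id, ann_id, rule, message) {
  tibble::tibble(
    doc_id = doc_id, ann_id = ann_id, rule = rule, message = message
  )
}

empty_violations <- function() {
  tibble::tibble(
    doc_id = character(), ann_id = character(),
    rule = character(), message = character()
  )
}

#' Validate a document against a schema
#'
#' Checks every annotation of a structurally sound document against the
#' scheme: label inventories (after alias resolution), relation endpoint
#' constraints, attribute hosting, trigger/event type agreement, and mutual
#' exclusivity of the intent/actuality attributes. Validation reports rather
#' than throws, so that non-conformant files can be loaded and diagnosed.
#'
#' Rule codes form a closed set: `unknown_entity_type`, `unknown_event_type`,
#' `unknown_relation_type`, `unknown_attribute_name`,
#' `unknown_argument_role`, `relation_endpoint_kind`,
#' `relation_endpoint_type`, `attribute_host_kind`, `trigger_type_mismatch`,
#' `intent_attribute_conflict`.
#'
#' @param schema An `mrira_schema`.
#' @param doc An [mrira_document()].
#' @return A tibble of violations (`doc_id`, `ann_id`, `rule`, `message`);
#'   zero rows if and only if the document conforms.
#' @export
validate_document <- function(schema, doc) {
  doc <- resolve_document(doc, schema)
  v <- list(empty_violations())
  ent_names <- schema$entity_types$name
  evt_names <- schema$event_types$name

  for (ent in doc$entities) {
    if (!ent$type %in% c(ent_names, evt_names)) {
      v[[length(v) + 1L]] <- violation_row(
        doc$doc_id, ent$id, "unknown_entity_type",
        sprintf("entity type '%s' is not in the schema", ent$type)
      )
    }
  }

  for (ev in doc$events) {
    if (!ev$type %in% evt_names) {
      v[[length(v) + 1L]] <- violation_row(
        doc$doc_id, ev$id, "unknown_event_type",
        sprintf("event type '%s' is not in the schema", ev$type)
      )
    } else {
      trig <- doc$entities[[ev$trigger]]
      if (!identical(trig$type, ev$type)) {
        v[[length(v) + 1L]] <- violation_row(
          doc$doc_id, ev$id, "trigger_type_mismatch",
          sprintf(
            "event type '%s' differs from trigger %s type '%s'",
            ev$type, trig$id, trig$type
          )
        )
      }
    }
    for (a in ev$args) {
      if (!a$role %in% schema$argument_roles) {
        v[[length(v) + 1L]] <- violation_row(
          doc$doc_id, ev$id, "unknown_argument_role",
          sprintf("argument role '%s' is not in the schema", a$role)
        )
      }
    }
  }

  for (rel in doc$relations) {
    if (schema$mismatch_enabled && identical(rel$type, schema$mismatch_name)) {
      for (endp in c(rel$source, rel$target)) {
        if (!endp %in% names(doc$events)) {
          v[[length(v) + 1L]] <- violation_row(
            doc$doc_id, rel$id, "relation_endpoint_kind",
            sprintf(
              "'%s' links events, but %s is not an event",
              schema$mismatch_name, endp
            )
          )
        }
      }
      next
    }
    if (!rel$type %in% schema$relations$name) {
      v[[length(v) + 1L]] <- violation_row(
        doc$doc_id, rel$id, "unknown_relation_type",
        sprintf("relation type '%s' is not in the schema", rel$type)
      )
      next
    }
    kinds_ok <- TRUE
    for (endp in c(rel$source, rel$target)) {
      if (!endp %in% names(doc$entities)) {
        v[[length(v) + 1L]] <- violation_row(
          doc$doc_id, rel$id, "relation_endpoint_kind",
          sprintf("relation endpoint %s is not an entity", endp)
        )
        kinds_ok <- FALSE
      }
    }
    if (!kinds_ok) next
    st <- doc$entities[[rel$source]]$type
    tt <- doc$entities[[rel$target]]$type
    allowed <- schema$relations[schema$relations$name == rel$type, ]
    if (!any(allowed$source == st & allowed$target == tt)) {
      v[[length(v) + 1L]] <- violation_row(
        doc$doc_id, rel$id, "relation_endpoint_type",
        sprintf(
          "relation '%s' does not allow ('%s' -> '%s')", rel$type, st, tt
        )
      )
    }
  }

  for (at in doc$attributes) {
    if (!at$name %in% schema$attribute_names) {
      v[[length(v) + 1L]] <- violation_row(
        doc$doc_id, at$id, "unknown_attribute_name",
        sprintf("attribute '%s' is not in the schema", at$name)
      )
    }
    if (!at$host %in% names(doc$events)) {
      v[[length(v) + 1L]] <- violation_row(
        doc$doc_id, at$id, "attribute_host_kind",
        sprintf("attribute host %s is not an event", at$host)
      )
    }
  }

  # at most one of the four intent/actuality attributes per event
  intent <- Filter(
    function(at) at$name %in% schema$intent_attributes && at$host %in% names(doc$events),
    doc$attributes
  )
  if (length(intent)) {
    hosts <- vapply(intent, function(at) at$host, character(1))
    for (h in unique(hosts)) {
      if (sum(hosts == h) > 1L) {
        v[[length(v) + 1L]] <- violation_row(
          doc$doc_id, h, "intent_attribute_conflict",
          sprintf(
            "event %s carries %d intent/actuality attributes (max 1)",
            h, sum(hosts == h)
          )
        )
      }
    }
  }

  out <- do.call(rbind, v)
  out[order(out$ann_id, out$rule), , drop = FALSE]
}

#' Validate a corpus
#'
#' @param schema An `mrira_schema`.
#' @param docs List of [mrira_document()]s.
#' @return Row-bound violations across all documents.
#' @export
validate_corpus <- function(schema, docs) {
  do.call(rbind, c(list(empty_violations()), lapply(docs, function(d) {
    validate_document(schema, d)
  })))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
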