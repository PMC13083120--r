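#' Summarise an annotated corpus
#'
#' Produces the standard per-type summary table of an annotated corpus: for
#' every schema type — including types with zero instances — the number of
#' annotations, the average number of words per annotation (exact and rounded
#' to integer, since published tables round), and the total word count over
#' annotations of that type. Argument-role and attribute rows report counts
#' only. The four intent/actuality attributes are also available summed as a
#' single row via the returned object's print method.
#'
#' Words are whitespace-delimited tokens of the covered surface text;
#' hyphenated tokens count as one word. Entity rows cover non-trigger
#' entities; event rows count events, with words taken from the trigger
#' surface.
#'
#' @param docs List of [mrira_document()]s.
#' @param schema An `mrira_schema` (labels are alias-resolved before
#'   counting).
#' @return An object of class `mrira_corpus_statistics`: a tibble with
#'   columns `level` (`entities`, `events`, `argument_roles`, `attributes`),
#'   `group` (schema category heading), `type`, `n_annotations`,
#'   `avg_words`, `avg_words_rounded`, `total_words` (the last three `NA`
#'   for roles and attributes).
#' @export
summarize_corpus <- function(docs, schema = default_schema()) {
  docs <- lapply(docs, resolve_document, schema = schema)
  n_words <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) {
      return(0L)
    }
    length(strsplit(s, "[[:space:]]+")[[1]])
  }

  ent_surfaces <- list()
  evt_surfaces <- list()
  role_counts <- stats::setNames(
    integer(length(schema$argument_roles)), schema$argument_roles
  )
  attr_counts <- stats::setNames(
    integer(length(schema$attribute_names)), schema$attribute_names
  )
  for (doc in docs) {
    for (ent in non_trigger_entities(doc)) {
      ent_surfaces[[ent$type]] <- c(ent_surfaces[[ent$type]], ent$surface)
    }
    for (ev in doc$events) {
      trig <- doc$entities[[ev$trigger]]
      evt_surfaces[[ev$type]] <- c(evt_surfaces[[ev$type]], trig$surface)
      for (a in ev$args) {
        if (a$role %in% names(role_counts)) {
          role_counts[[a$role]] <- role_counts[[a$role]] + 1L
        }
      }
    }
    for (at in doc$attributes) {
      if (at$name %in% names(attr_counts)) {
        attr_counts[[at$name]] <- attr_counts[[at$name]] + 1L
      }
    }
  }

  word_rows <- function(level, types, groups, surfaces) {
    do.call(rbind, lapply(seq_along(types), function(i) {
      s <- surfaces[[types[[i]]]]
      n <- length(s)
      wc <- if (n) vapply(s, n_words, integer(1)) else integer()
      tibble::tibble(
        level = level, group = groups[[i]], type = types[[i]],
        n_annotations = n,
        avg_words = if (n) mean(wc) else 0,
        avg_words_rounded = if (n) as.integer(round(mean(wc))) else 0L,
        total_words = sum(wc)
      )
    }))
  }

  out <- rbind(
    word_rows(
      "entities", schema$entity_types$name, schema$entity_types$group,
      ent_surfaces
    ),
    word_rows(
      "events", schema$event_types$name, schema$event_types$group,
      evt_surfaces
    ),
    tibble::tibble(
      level = "argument_roles", group = "argument_roles",
      type = names(role_counts), n_annotations = unname(role_counts),
      avg_words = NA_real_, avg_words_rounded = NA_integer_,
      total_words = NA_integer_
    ),
    tibble::tibble(
      level = "attributes", group = "attributes",
      type = names(attr_counts), n_annotations = unname(attr_counts),
      avg_words = NA_real_, avg_words_rounded = NA_integer_,
      total_words = NA_integer_
    )
  )
  structure(out,
    class = c("mrira_corpus_statistics", class(out)),
    n_documents = length(docs)
  )
}

#' @export
print.mrira_corpus_statistics <- function(x, ...) {
  cat(sprintf(
    "Corpus statistics over %d document(s)\n", attr(x, "n_documents")
  ))
  NextMethod(n = nrow(x))
  invisible(x)
}
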