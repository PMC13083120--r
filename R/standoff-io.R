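#' Parse a standoff-annotated document
#'
#' Reads one narrative and its BRAT-style standoff annotation payload into an
#' [mrira_document()]. The dialect is tab-separated lines whose identifier
#' prefix determines the record kind: `T` (text-bound entity or event
#' trigger), `E` (event), `R` (relation), `A` (attribute), `#` (annotator
#' note, preserved verbatim). Any other prefix is rejected.
#'
#' Offsets are 0-based, half-open character (code point) offsets into
#' `text_content`. Discontinuous spans use semicolon-separated fragment
#' pairs (`"0 4;10 14"`); their stored surface is the fragment texts joined
#' by a single space. The stored surface of every `T` line is checked against
#' the text: a mismatch is an error, not a warning, because it means the
#' offsets index a different text than the one supplied.
#'
#' Annotation lines may appear in any order; references are resolved after
#' all lines are read.
#'
#' @param text_content The narrative text the annotation offsets index into.
#' @param ann_content The standoff annotation payload (one record per line;
#'   may be empty).
#' @param doc_id Document name.
#' @return An [mrira_document()].
#' @examples
#' doc <- parse_document("morphine 10 mg", "T1\tDrug name 0 8\tmorphine", "ex")
#' doc$entities$T1$type
#' @export
parse_document <- function(text_content, ann_content, doc_id = "doc") {
  stopifnot(is.character(text_content), length(text_content) == 1L)
  lines <- if (identical(ann_content, "")) {
    character()
  } else {
    strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  }
  entities <- list()
  events <- list()
  relations <- list()
  attributes <- list()
  notes <- character()

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      notes <- c(notes, line)
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- fields[[1]]
    kind <- substr(id, 1L, 1L)
    dup <- id %in% c(names(entities), names(events), names(relations), names(attributes))
    if (kind %in% c("T", "E", "R", "A") && dup) {
      stop(sprintf("line %d: duplicate annotation identifier '%s'", i, id),
        call. = FALSE
      )
    }
    if (kind == "T") {
      entities[[id]] <- parse_t_line(fields, i)
    } else if (kind == "E") {
      events[[id]] <- parse_e_line(fields, i)
    } else if (kind == "R") {
      relations[[id]] <- parse_r_line(fields, i)
    } else if (kind == "A") {
      attributes[[id]] <- parse_a_line(fields, i)
    } else {
      stop(sprintf(
        "line %d: unknown annotation line prefix '%s' (expected T/E/R/A/#)",
        i, kind
      ), call. = FALSE)
    }
  }

  # fill in surfaces for T lines that omitted the text field, then let the
  # document constructor enforce offsets/surface/reference integrity
  n_text <- nchar(text_content)
  entities <- lapply(entities, function(ent) {
    validate_span(ent$span, n_text, where = sprintf("entity %s", ent$id))
    if (is.na(ent$surface)) ent$surface <- span_surface(ent$span, text_content)
    ent
  })

  mrira_document(
    doc_id = doc_id, text = text_content,
    entities = entities, events = events,
    relations = relations, attributes = attributes, notes = notes
  )
}

parse_t_line <- function(fields, lineno) {
  if (length(fields) < 2L || length(fields) > 3L) {
    stop(sprintf(
      "line %d: text-bound annotation needs 2-3 tab-separated fields, got %d",
      lineno, length(fields)
    ), call. = FALSE)
  }
  # field 2 is "<type> <offsets>"; the type may itself contain spaces, so
  # split at the first token where the offset grammar starts
  m <- regmatches(
    fields[[2]],
    regexec("^(.*?) ([0-9]+ [0-9]+(?:;[0-9]+ [0-9]+)*)$", fields[[2]])
  )[[1]]
  if (length(m) != 3L || !nzchar(m[[2]])) {
    stop(sprintf(
      "line %d: cannot parse type/offsets from '%s'",
      lineno, fields[[2]]
    ), call. = FALSE)
  }
  sp <- parse_span_offsets(m[[3]])
  surface <- if (length(fields) == 3L) fields[[3]] else NA_character_
  new_entity(fields[[1]], m[[2]], sp, surface)
}

# tokens of an E-line body are "Name:Id"; a Name may contain spaces, so glue
# space-split pieces until one carries the colon
split_role_tokens <- function(body, lineno) {
  raw <- strsplit(trimws(body), " ", fixed = TRUE)[[1]]
  raw <- raw[nzchar(raw)]
  out <- character()
  buf <- character()
  for (tok in raw) {
    buf <- c(buf, tok)
    if (grepl(":", tok, fixed = TRUE)) {
      out <- c(out, paste(buf, collapse = " "))
      buf <- character()
    }
  }
  if (length(buf)) {
    stop(sprintf("line %d: malformed role:identifier token near '%s'",
      lineno, paste(buf, collapse = " ")
    ), call. = FALSE)
  }
  out
}

parse_e_line <- function(fields, lineno) {
  if (length(fields) != 2L) {
    stop(sprintf(
      "line %d: event line needs 2 tab-separated fields, got %d",
      lineno, length(fields)
    ), call. = FALSE)
  }
  toks <- split_role_tokens(fields[[2]], lineno)
  if (!length(toks)) {
    stop(sprintf("line %d: event line has no trigger token", lineno),
      call. = FALSE
    )
  }
  pairs <- lapply(toks, function(tok) {
    # names never contain colons in this dialect, identifiers never do either
    k <- max(gregexpr(":", tok, fixed = TRUE)[[1]])
    list(name = substr(tok, 1L, k - 1L), id = substr(tok, k + 1L, nchar(tok)))
  })
  head <- pairs[[1]]
  args <- lapply(pairs[-1], function(p) list(role = p$name, filler = p$id))
  new_event(fields[[1]], head$name, head$id, args)
}

parse_r_line <- function(fields, lineno) {
  if (length(fields) != 2L) {
    stop(sprintf(
      "line %d: relation line needs 2 tab-separated fields, got %d",
      lineno, length(fields)
    ), call. = FALSE)
  }
  m <- regmatches(
    fields[[2]],
    regexec("^(.*) Arg1:(\\S+) Arg2:(\\S+)$", fields[[2]])
  )[[1]]
  if (length(m) != 4L) {
    stop(sprintf(
      "line %d: cannot parse relation '%s' (expected '<type> Arg1:<id> Arg2:<id>')",
      lineno, fields[[2]]
    ), call. = FALSE)
  }
  new_relation(fields[[1]], m[[2]], m[[3]], m[[4]])
}

parse_a_line <- function(fields, lineno) {
  if (length(fields) != 2L) {
    stop(sprintf(
      "line %d: attribute line needs 2 tab-separated fields, got %d",
      lineno, length(fields)
    ), call. = FALSE)
  }
  toks <- strsplit(trimws(fields[[2]]), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  host_pos <- which(grepl("^[TER][0-9]+$", toks))
  if (!length(host_pos)) {
    stop(sprintf("line %d: attribute line has no host identifier", lineno),
      call. = FALSE
    )
  }
  host_pos <- host_pos[[1]]
  if (host_pos == 1L) {
    stop(sprintf("line %d: attribute line has no name", lineno), call. = FALSE)
  }
  name <- paste(toks[seq_len(host_pos - 1L)], collapse = " ")
  value <- if (host_pos < length(toks)) {
    paste(toks[seq(host_pos + 1L, length(toks))], collapse = " ")
  } else {
    NULL
  }
  new_attribute(fields[[1]], name, toks[[host_pos]], value)
}

#' Serialize a document to standoff format
#'
#' Emits the annotation payload of a document as standoff lines such that
#' `parse_document(text, serialize_document(doc))` reproduces the document
#' exactly, identifier for identifier. Discontinuous spans are written with
#' semicolon-separated fragment pairs. Note lines are emitted verbatim, after
#' the annotations.
#'
#' @param doc An [mrira_document()] whose structural invariants hold
#'   (serialization re-checks them and refuses otherwise).
#' @return A single string: the `.ann` file content (empty string for a
#'   document with no annotations).
#' @export
serialize_document <- function(doc) {
  check_document_integrity(doc)
  lines <- character()
  for (ent in doc$entities) {
    lines <- c(lines, sprintf(
      "%s\t%s %s\t%s",
      ent$id, ent$type, span_offsets_string(ent$span), ent$surface
    ))
  }
  for (ev in doc$events) {
    toks <- sprintf("%s:%s", ev$type, ev$trigger)
    for (a in ev$args) toks <- c(toks, sprintf("%s:%s", a$role, a$filler))
    lines <- c(lines, sprintf("%s\t%s", ev$id, paste(toks, collapse = " ")))
  }
  for (rel in doc$relations) {
    lines <- c(lines, sprintf(
      "%s\t%s Arg1:%s Arg2:%s", rel$id, rel$type, rel$source, rel$target
    ))
  }
  for (at in doc$attributes) {
    body <- if (is.null(at$value)) {
      sprintf("%s %s", at$name, at$host)
    } else {
      sprintf("%s %s %s", at$name, at$host, at$value)
    }
    lines <- c(lines, sprintf("%s\t%s", at$id, body))
  }
  lines <- c(lines, doc$notes)
  paste(lines, collapse = "\n")
}

#' Read a corpus of paired text and annotation files
#'
#' Reads every `.txt`/`.ann` pair in a directory (or an explicit set of
#' paths) into a named list of documents, keyed by basename. An annotation
#' file without its text partner — or vice versa — is an error naming the
#' orphan(s): a silent half-read corpus would corrupt every downstream count.
#'
#' @param dir Directory containing `.txt` and `.ann` files sharing basenames.
#' @return Named list of [mrira_document()]s, keyed by basename (sorted).
#'   An empty directory yields an empty list.
#' @export
read_corpus <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: '%s'", dir))
  txt <- list.files(dir, pattern = "\\.txt$")
  ann <- list.files(dir, pattern = "\\.ann$")
  base_txt <- sub("\\.txt$", "", txt)
  base_ann <- sub("\\.ann$", "", ann)
  orphans <- c(
    sprintf("%s.txt", setdiff(base_txt, base_ann)),
    sprintf("%s.ann", setdiff(base_ann, base_txt))
  )
  if (length(orphans)) {
    stop(sprintf(
      "unpaired file(s) in '%s': %s", dir, paste(orphans, collapse = ", ")
    ), call. = FALSE)
  }
  bases <- sort(base_txt)
  docs <- lapply(bases, function(b) {
    text <- read_file_utf8(file.path(dir, paste0(b, ".txt")))
    anns <- read_file_utf8(file.path(dir, paste0(b, ".ann")))
    parse_document(text, anns, doc_id = b)
  })
  names(docs) <- bases
  docs
}

#' Write a corpus as paired text and annotation files
#'
#' @param docs Named list of [mrira_document()]s (names become basenames; the
#'   document's own `doc_id` is used when the list is unnamed).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written basenames.
#' @export
write_corpus <- function(docs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bases <- names(docs)
  if (is.null(bases)) bases <- vapply(docs, function(d) d$doc_id, character(1))
  for (i in seq_along(docs)) {
    write_file_utf8(docs[[i]]$text, file.path(dir, paste0(bases[[i]], ".txt")))
    write_file_utf8(
      serialize_document(docs[[i]]),
      file.path(dir, paste0(bases[[i]], ".ann"))
    )
  }
  invisible(bases)
}

read_file_utf8 <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  raw <- readBin(path, "raw", file.info(path)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) stop(sprintf("'%s' is not valid UTF-8", path))
  # normalise line endings; strip a single trailing newline so that
  # write(read(x)) == x for files we wrote ourselves
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  sub("\n$", "", txt)
}

write_file_utf8 <- function(content, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(paste0(content, "\n"))), con)
  invisible(path)
}
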