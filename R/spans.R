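#' Text spans
#'
#' A text span is an ordered set of one or more fragments, each a pair of
#' 0-based, half-open character offsets `[start, end)` into the document
#' text. Offsets count Unicode code points, not bytes. Most annotations are
#' single-fragment; discontinuous annotations carry several fragments, which
#' must be sorted and non-overlapping.
#'
#' @param start,end Integer vectors of equal length giving fragment
#'   boundaries (0-based, half-open).
#' @return An object of class `mrira_span`: a two-column integer matrix with
#'   columns `start` and `end`, one row per fragment.
#' @examples
#' span(0, 8)
#' span(c(0, 10), c(4, 14)) # discontinuous
#' @export
span <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end) || length(start) == 0) {
    stop("span: 'start' and 'end' must be non-empty and of equal length")
  }
  m <- cbind(start = start, end = end)
  validate_span(m)
  structure(m, class = c("mrira_span", class(m)))
}

validate_span <- function(m, text_length = NULL, where = "span") {
  start <- m[, 1L]
  end <- m[, 2L]
  if (any(is.na(start)) || any(is.na(end))) {
    stop(sprintf("%s: offsets must be integers", where))
  }
  if (any(start >= end)) {
    stop(sprintf("%s: every fragment must satisfy start < end", where))
  }
  if (any(start < 0L)) {
    stop(sprintf("%s: offsets must be non-negative", where))
  }
  if (nrow(m) > 1L) {
    if (is.unsorted(start, strictly = TRUE)) {
      stop(sprintf("%s: fragments must be sorted by start offset", where))
    }
    if (any(end[-nrow(m)] > start[-1L])) {
      stop(sprintf("%s: fragments must not overlap", where))
    }
  }
  if (!is.null(text_length) && any(end > text_length)) {
    stop(sprintf("%s: offset beyond end of text (length %d)", where, text_length))
  }
  invisible(m)
}

#' @export
print.mrira_span <- function(x, ...) {
  cat("<span ", span_offsets_string(x), ">\n", sep = "")
  invisible(x)
}

# "0 8" / "0 4;10 14" — the standoff dialect's offset syntax
span_offsets_string <- function(sp) {
  paste(sprintf("%d %d", sp[, 1L], sp[, 2L]), collapse = ";")
}

parse_span_offsets <- function(s) {
  frags <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- lapply(frags, function(f) {
    p <- strsplit(trimws(f), "[ \t]+")[[1]]
    if (length(p) != 2L || !all(grepl("^[0-9]+$", p))) {
      stop(sprintf("malformed span offsets: '%s'", s))
    }
    as.integer(p)
  })
  m <- do.call(rbind, parts)
  span(m[, 1L], m[, 2L])
}

# covered text: fragments joined by a single space (standoff convention for
# discontinuous spans); tabs/newlines inside a span become spaces, since the
# surface lives in a tab-separated single-line field
span_surface <- function(sp, text) {
  pieces <- vapply(
    seq_len(nrow(sp)),
    function(i) substr(text, sp[i, 1L] + 1L, sp[i, 2L]),
    character(1)
  )
  gsub("[\t\n\r]", " ", paste(pieces, collapse = " "))
}

span_length <- function(sp) sum(sp[, 2L] - sp[, 1L])

# character overlap between two (possibly discontinuous) spans:
# any-fragment-vs-any-fragment
span_overlap <- function(a, b) {
  total <- 0L
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    total <- total + sum(pmax(0L, hi - lo))
  }
  total
}

spans_identical <- function(a, b) {
  nrow(a) == nrow(b) && all(a == b)
}
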