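#' Span matching criteria
#'
#' Two text-bound annotations match under the *strict* criterion when their
#' fragment lists are identical and their (alias-resolved) types are equal;
#' under the *relaxed* criterion when the types are equal and some fragment
#' of one overlaps some fragment of the other by at least one character.
#'
#' @param a,b Entity records (as stored in an [mrira_document()]): lists with
#'   a `span` and a `type`.
#' @param criterion `"strict"` or `"relaxed"`.
#' @return Logical scalar.
#' @examples
#' x <- new_entity_record("Drug name", span(0, 8), "morphine")
#' y <- new_entity_record("Drug name", span(0, 16), "morphine sulfate")
#' span_match(x, y, "strict") # FALSE
#' span_match(x, y, "relaxed") # TRUE
#' @export
span_match <- function(a, b, criterion = c("strict", "relaxed")) {
  criterion <- match.arg(criterion)
  if (!identical(a$type, b$type)) {
    return(FALSE)
  }
  if (criterion == "strict") {
    spans_identical(a$span, b$span)
  } else {
    span_overlap(a$span, b$span) >= 1L
  }
}

#' Construct a bare entity record
#'
#' Helper for building typed spans outside a document (useful for quick
#' matching experiments and tests).
#'
#' @param type Type label.
#' @param sp A [span()].
#' @param surface Covered text (optional).
#' @return An entity record.
#' @export
new_entity_record <- function(type, sp, surface = "") {
  new_entity(id = NA_character_, type = type, sp = sp, surface = surface)
}

# admissibility matrix + character-overlap weights for two annotation
# collections under a pairwise predicate
admissible_pairs <- function(reference, response, match_fun, overlap_fun) {
  n_ref <- length(reference)
  n_res <- length(response)
  adm <- matrix(FALSE, n_ref, n_res)
  w <- matrix(0, n_ref, n_res)
  for (i in seq_len(n_ref)) {
    for (j in seq_len(n_res)) {
      if (match_fun(reference[[i]], response[[j]])) {
        adm[i, j] <- TRUE
        w[i, j] <- overlap_fun(reference[[i]], response[[j]])
      }
    }
  }
  list(adm = adm, w = w)
}

entity_overlap <- function(a, b) span_overlap(a$span, b$span)

correspondence <- function(pairs, ref_ids, res_ids) {
  matched_ref <- if (nrow(pairs)) pairs$reference else character()
  matched_res <- if (nrow(pairs)) pairs$response else character()
  structure(
    list(
      pairs = pairs,
      unmatched_reference = setdiff(ref_ids, matched_ref),
      unmatched_response = setdiff(res_ids, matched_res)
    ),
    class = "mrira_correspondence"
  )
}

empty_pairs <- function() {
  tibble::tibble(reference = character(), response = character())
}

#' Align two annotators' annotations one-to-one
#'
#' Finds a maximum-cardinality one-to-one matching between a reference
#' annotator's annotations and a response annotator's annotations, over the
#' pairs admissible under the given criterion (or an arbitrary pairwise
#' predicate). Among maximum-cardinality matchings, matchings with larger
#' total character overlap are preferred, and remaining ties are broken
#' deterministically in favour of pairing earlier-listed (for spans:
#' earlier-starting) reference annotations.
#'
#' The optimum is found by maximum-weight bipartite matching with weights
#' that make one extra pair worth more than all overlap combined, so greedy
#' undercounting on crossing overlaps cannot occur.
#'
#' @param reference,response Named lists of annotation records (names are the
#'   annotation identifiers; unnamed lists are keyed by position).
#' @param criterion `"strict"` or `"relaxed"`; used when `match_fun` is the
#'   default [span_match()].
#' @param match_fun Pairwise admissibility predicate `(a, b) -> logical`.
#' @param overlap_fun Tie-breaking overlap weight `(a, b) -> numeric`;
#'   defaults to character overlap for spans, 0 otherwise.
#' @return An `mrira_correspondence`: `pairs` (tibble of reference/response
#'   id pairs), `unmatched_reference`, `unmatched_response`. The pairs and
#'   unmatched sets partition both sides exactly.
#' @seealso [brute_force_align()] for the exhaustive oracle used in tests.
#' @export
align_annotations <- function(reference, response,
                              criterion = c("strict", "relaxed"),
                              match_fun = NULL, overlap_fun = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(match_fun)) {
    match_fun <- function(a, b) span_match(a, b, criterion)
    if (is.null(overlap_fun)) overlap_fun <- entity_overlap
  }
  if (is.null(overlap_fun)) overlap_fun <- function(a, b) 0
  ref_ids <- collection_ids(reference)
  res_ids <- collection_ids(response)
  n_ref <- length(reference)
  n_res <- length(response)
  if (n_ref == 0L || n_res == 0L) {
    return(correspondence(empty_pairs(), ref_ids, res_ids))
  }

  ap <- admissible_pairs(reference, response, match_fun, overlap_fun)
  idx <- which(ap$adm, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(correspondence(empty_pairs(), ref_ids, res_ids))
  }

  # integer weights: K dominates total overlap (cardinality first), overlap
  # second; a tiny per-pair bonus for earlier reference items makes the
  # tie-break deterministic without ever outweighing one unit of overlap
  overlaps <- ap$w[idx]
  k_card <- sum(overlaps) + 1
  n_pairs <- nrow(idx)
  pref <- order(idx[, 1L], idx[, 2L]) # preference rank by (ref, res) position
  eps <- numeric(n_pairs)
  eps[pref] <- (n_pairs - seq_len(n_pairs)) / (2 * n_pairs * max(n_ref, n_res) + 2)
  weights <- k_card + overlaps + eps

  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n_ref), rep(TRUE, n_res)),
    edges = as.vector(rbind(idx[, 1L], n_ref + idx[, 2L])),
    directed = FALSE
  )
  m <- igraph::max_bipartite_match(g, weights = weights)
  mate <- m$matching[seq_len(n_ref)]
  matched_i <- which(!is.na(mate))
  pairs <- tibble::tibble(
    reference = ref_ids[matched_i],
    response = res_ids[as.integer(mate[matched_i]) - n_ref]
  )
  correspondence(pairs, ref_ids, res_ids)
}

collection_ids <- function(x) {
  if (!is.null(names(x))) {
    return(names(x))
  }
  ids <- vapply(x, function(a) a$id %||% NA_character_, character(1))
  if (any(is.na(ids))) ids <- as.character(seq_along(x))
  ids
}

#' Exhaustive alignment oracle
#'
#' Enumerates every one-to-one matching between the two collections and
#' returns an optimum under the same objective as [align_annotations()]
#' (cardinality, then total overlap, then earliest reference preference).
#' Exponential in the input size, hence the hard cap; intended as an
#' independent correctness oracle in tests, never for production scoring.
#'
#' @inheritParams align_annotations
#' @return An `mrira_correspondence`.
#' @export
brute_force_align <- function(reference, response,
                              criterion = c("strict", "relaxed"),
                              match_fun = NULL, overlap_fun = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(match_fun)) {
    match_fun <- function(a, b) span_match(a, b, criterion)
    if (is.null(overlap_fun)) overlap_fun <- entity_overlap
  }
  if (is.null(overlap_fun)) overlap_fun <- function(a, b) 0
  if (length(reference) + length(response) > 12L) {
    stop("brute_force_align: instance too large (> 12 annotations in total)")
  }
  ref_ids <- collection_ids(reference)
  res_ids <- collection_ids(response)
  n_ref <- length(reference)
  n_res <- length(response)
  if (n_ref == 0L || n_res == 0L) {
    return(correspondence(empty_pairs(), ref_ids, res_ids))
  }
  ap <- admissible_pairs(reference, response, match_fun, overlap_fun)

  best <- list(card = -1L, overlap = -Inf, assign = integer())
  assign <- rep(NA_integer_, n_ref)
  used <- rep(FALSE, n_res)

  consider <- function(assign) {
    card <- sum(!is.na(assign))
    ov <- sum(ap$w[cbind(which(!is.na(assign)), assign[!is.na(assign)])])
    better <- card > best$card ||
      (card == best$card && ov > best$overlap)
    # ties: keep the first found; recursion explores lower (ref, res)
    # indices first, matching the production tie-break preference
    if (better) best <<- list(card = card, overlap = ov, assign = assign)
  }

  recurse <- function(i) {
    if (i > n_ref) {
      consider(assign)
      return(invisible())
    }
    for (j in seq_len(n_res)) {
      if (ap$adm[i, j] && !used[j]) {
        assign[i] <<- j
        used[j] <<- TRUE
        recurse(i + 1L)
        assign[i] <<- NA_integer_
        used[j] <<- FALSE
      }
    }
    recurse(i + 1L) # leave reference item i unmatched
  }
  recurse(1L)

  matched_i <- which(!is.na(best$assign))
  pairs <- tibble::tibble(
    reference = ref_ids[matched_i],
    response = res_ids[best$assign[matched_i]]
  )
  correspondence(pairs, ref_ids, res_ids)
}

#' @export
print.mrira_correspondence <- function(x, ...) {
  cat(sprintf(
    "<correspondence: %d pairs, %d unmatched reference, %d unmatched response>\n",
    nrow(x$pairs), length(x$unmatched_reference), length(x$unmatched_response)
  ))
  invisible(x)
}
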