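#' Entity and relation inventories
#'
#' The closed annotation schema: nine clinical entity types and seven positive
#' relation types plus the `None` label. `OtherSS` ("other signs and
#' symptoms") is annotated as an entity but never participates in a relation.
#'
#' @format Character vectors of type names.
#' @name schema
NULL

#' @rdname schema
#' @export
ENTITY_TYPES <- c(
  "Medication", "Indication", "ADE", "Severity",
  "Dosage", "Route", "Frequency", "Duration", "OtherSS"
)

#' @rdname schema
#' @export
RELATION_TYPES <- c(
  "Dosage", "Route", "Frequency", "Duration",
  "Indication", "Adverse", "Severity"
)

#' @rdname schema
#' @export
NONE_LABEL <- "None"

#' @rdname schema
#' @export
ALL_LABELS <- c(RELATION_TYPES, NONE_LABEL)

# Unordered entity-type pair licensed by each positive relation type.
RELATION_SCHEMA <- list(
  Dosage     = c("Medication", "Dosage"),
  Route      = c("Medication", "Route"),
  Frequency  = c("Medication", "Frequency"),
  Duration   = c("Medication", "Duration"),
  Indication = c("Medication", "Indication"),
  Adverse    = c("Medication", "ADE"),
  Severity   = c("Severity", "ADE")
)

#' Entity-type pair licensed by a relation type
#'
#' @param label A positive relation type.
#' @return Character vector of the two entity types (unordered).
#' @export
relation_schema <- function(label) {
  if (!label %in% RELATION_TYPES) {
    stop_relex(sprintf("unknown relation type '%s'", label), "relex_schema_error")
  }
  RELATION_SCHEMA[[label]]
}

#' Construct an annotated document
#'
#' An annotated document bundles raw note text with its tokenization, entity
#' mentions and gold relations. Token and character indices are 0-based;
#' character ends are exclusive; token spans are inclusive.
#'
#' @param doc_id Document identifier.
#' @param text Raw note text.
#' @param tokens Data frame with columns `surface`, `char_start`, `char_end`,
#'   `sentence_index`, `token_index`.
#' @param mentions Data frame with columns `id`, `etype`, `first_token`,
#'   `last_token`, `text`.
#' @param relations Data frame with columns `id`, `label`, `left_id`,
#'   `right_id` (left precedes right in document order).
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `relex_document`.
#' @export
relex_document <- function(doc_id, text, tokens, mentions = NULL,
                           relations = NULL, validate = TRUE) {
  if (is.null(mentions)) {
    mentions <- data.frame(
      id = character(), etype = character(), first_token = integer(),
      last_token = integer(), text = character(), stringsAsFactors = FALSE
    )
  }
  if (is.null(relations)) {
    relations <- data.frame(
      id = character(), label = character(), left_id = character(),
      right_id = character(), stringsAsFactors = FALSE
    )
  }
  doc <- structure(
    list(doc_id = doc_id, text = text, tokens = tokens,
         mentions = mentions, relations = relations),
    class = "relex_document"
  )
  if (validate) validate_document(doc)
  doc
}

#' Validate annotated-document invariants
#'
#' Checks token-span bounds, schema membership of entity and relation types,
#' OtherSS exclusion, document-order of relation arguments, and absence of
#' duplicate positive relations.
#'
#' @param doc A `relex_document`.
#' @return The document, invisibly; signals an error on violation.
#' @export
validate_document <- function(doc) {
  tk <- doc$tokens
  mn <- doc$mentions
  rl <- doc$relations
  n_tok <- nrow(tk)
  if (n_tok > 0) {
    if (any(tk$char_start >= tk$char_end)) {
      stop_relex("token with empty character span", "relex_validation_error")
    }
    if (n_tok > 1 && any(diff(tk$token_index) <= 0)) {
      stop_relex("token_index not strictly increasing", "relex_validation_error")
    }
    if (n_tok > 1 && any(diff(tk$sentence_index) < 0)) {
      stop_relex("sentence_index decreasing", "relex_validation_error")
    }
  }
  if (nrow(mn) > 0) {
    if (anyDuplicated(mn$id)) {
      stop_relex("duplicate mention id", "relex_validation_error")
    }
    bad <- !mn$etype %in% ENTITY_TYPES
    if (any(bad)) {
      stop_relex(sprintf("unknown entity type '%s'", mn$etype[bad][1]),
                 "relex_validation_error")
    }
    if (any(mn$first_token > mn$last_token)) {
      stop_relex("mention with first_token > last_token", "relex_validation_error")
    }
    if (any(mn$first_token < 0) || any(mn$last_token >= n_tok)) {
      stop_relex("mention token span outside document", "relex_validation_error")
    }
  }
  if (nrow(rl) > 0) {
    if (!all(rl$label %in% RELATION_TYPES)) {
      stop_relex("relation with unknown label", "relex_validation_error")
    }
    miss <- !(rl$left_id %in% mn$id) | !(rl$right_id %in% mn$id)
    if (any(miss)) {
      stop_relex(sprintf("relation %s references a missing mention",
                         rl$id[miss][1]), "relex_dangling_argument_error")
    }
    li <- match(rl$left_id, mn$id)
    ri <- match(rl$right_id, mn$id)
    if (any(mn$first_token[li] > mn$first_token[ri])) {
      stop_relex("relation left argument does not precede right argument",
                 "relex_validation_error")
    }
    if (any(mn$etype[li] == "OtherSS") || any(mn$etype[ri] == "OtherSS")) {
      stop_relex("OtherSS mention participates in a relation",
                 "relex_validation_error")
    }
    key <- paste(rl$left_id, rl$right_id, rl$label)
    if (anyDuplicated(key)) {
      stop_relex("duplicate positive relation", "relex_validation_error")
    }
    for (i in seq_len(nrow(rl))) {
      types <- sort(c(mn$etype[li[i]], mn$etype[ri[i]]))
      want <- sort(RELATION_SCHEMA[[rl$label[i]]])
      if (!identical(types, want)) {
        stop_relex(
          sprintf("relation %s (%s) links %s-%s, schema requires %s-%s",
                  rl$id[i], rl$label[i], types[1], types[2], want[1], want[2]),
          "relex_validation_error"
        )
      }
    }
  }
  invisible(doc)
}

#' @export
print.relex_document <- function(x, ...) {
  cat(sprintf("<relex_document %s: %d tokens, %d mentions, %d relations>\n",
              x$doc_id, nrow(x$tokens), nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

#' @keywords internal
mention_row <- function(doc, id) {
  i <- match(id, doc$mentions$id)
  if (is.na(i)) {
    stop_relex(sprintf("mention '%s' not in document '%s'", id, doc$doc_id),
               "relex_lookup_error")
  }
  doc$mentions[i, , drop = FALSE]
}

#' Order two mention ids by document position
#' @keywords internal
order_pair <- function(doc, a_id, b_id) {
  a <- mention_row(doc, a_id)
  b <- mention_row(doc, b_id)
  if (a$first_token <= b$first_token) c(a_id, b_id) else c(b_id, a_id)
}

#' Index a list of documents by doc_id
#'
#' @param docs A list of `relex_document` objects (or a corpus split).
#' @return A named list keyed by `doc_id`.
#' @export
doc_index <- function(docs) {
  stats::setNames(docs, vapply(docs, function(d) d$doc_id, character(1)))
}
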