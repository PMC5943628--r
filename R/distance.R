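#' Token distance between two entity mentions
#'
#' The number of tokens lying strictly between the last token of the earlier
#' mention and the first token of the later mention. Adjacent mentions have
#' distance 0; the measure is symmetric in argument order. Overlapping
#' mentions have no defined distance and raise an error.
#'
#' @param doc A `relex_document`.
#' @param a_id,b_id Mention ids in `doc`.
#' @return Non-negative integer distance.
#' @export
token_distance <- function(doc, a_id, b_id) {
  a <- mention_row(doc, a_id)
  b <- mention_row(doc, b_id)
  if (a$first_token <= b$last_token && b$first_token <= a$last_token) {
    stop_relex(sprintf("mentions '%s' and '%s' overlap", a_id, b_id),
               "relex_overlap_error")
  }
  if (a$first_token > b$first_token) {
    tmp <- a; a <- b; b <- tmp
  }
  as.integer(b$first_token - a$last_token - 1L)
}

#' Number of entity mentions lying between a mention pair
#'
#' Counts other mentions whose token spans fall entirely between the two
#' mentions of a pair. Symmetric in argument order.
#'
#' @inheritParams token_distance
#' @return Non-negative integer count.
#' @export
mentions_between <- function(doc, a_id, b_id) {
  a <- mention_row(doc, a_id)
  b <- mention_row(doc, b_id)
  if (a$first_token <= b$last_token && b$first_token <= a$last_token) {
    stop_relex(sprintf("mentions '%s' and '%s' overlap", a_id, b_id),
               "relex_overlap_error")
  }
  if (a$first_token > b$first_token) {
    tmp <- a; a <- b; b <- tmp
  }
  mn <- doc$mentions
  others <- mn$id != a$id & mn$id != b$id
  sum(others & mn$first_token > a$last_token & mn$last_token < b$first_token)
}
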