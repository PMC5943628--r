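#' Tokenize raw note text
#'
#' Whitespace- and punctuation-splitting tokenizer with simple sentence
#' segmentation. Tokens are maximal runs of word characters
#' (`[A-Za-z0-9_]`) or single punctuation characters, so punctuation is
#' always split from words. The sentence index increments after a
#' sentence-final `.`, `!` or `?` that is followed by whitespace (or ends the
#' text).
#'
#' @param raw_text Note text; must contain at least one non-whitespace
#'   character.
#' @return A data frame of tokens with columns `surface`, `char_start`
#'   (0-based), `char_end` (exclusive), `sentence_index`, `token_index`.
#' @examples
#' tokenize("He has severe diarrhea.")
#' @export
tokenize <- function(raw_text) {
  if (length(raw_text) != 1 || is.na(raw_text) || !nzchar(trimws(raw_text))) {
    stop_relex("cannot tokenize empty or whitespace-only text",
               "relex_empty_document_error")
  }
  m <- gregexpr("[A-Za-z0-9_]+|[^A-Za-z0-9_[:space:]]", raw_text)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surfaces <- substring(raw_text, starts, starts + lens - 1L)
  n <- length(surfaces)
  ends0 <- starts + lens - 1L # 1-based inclusive end
  # sentence segmentation: a token in {. ! ?} whose following character is
  # whitespace or end-of-text closes the current sentence
  nxt <- substring(raw_text, ends0 + 1L, ends0 + 1L)
  closes <- surfaces %in% c(".", "!", "?") & (nxt == "" | grepl("^[[:space:]]$", nxt))
  sentence_index <- c(0L, cumsum(closes)[-n])
  data.frame(
    surface = surfaces,
    char_start = starts - 1L,
    char_end = starts - 1L + lens,
    sentence_index = as.integer(sentence_index),
    token_index = seq_len(n) - 1L,
    stringsAsFactors = FALSE
  )
}
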