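#' Load a word-embedding table in word2vec text format
#'
#' The format is a header line `"V D"` (vocabulary size and dimension)
#' followed by `V` lines of a word and `D` floats. Duplicate words are
#' resolved last-wins with a warning; a ragged vector length is a format
#' error. Words absent from the table are mapped to `unk_vector` at lookup
#' time (the zero vector by default).
#'
#' @param content A single string with the file content, or a path to a file.
#' @return An object of class `relex_embeddings` with fields `dimension`,
#'   `vectors` (matrix, words as rownames) and `unk_vector`.
#' @export
load_embeddings <- function(content) {
  lines <- read_resource_lines(content)
  if (length(lines) < 1) {
    stop_relex("empty embedding file", "relex_format_error")
  }
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) != 2) {
    stop_relex("embedding header must be 'V D'", "relex_format_error")
  }
  dim <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  lens <- lengths(parts)
  if (any(lens != dim + 1)) {
    stop_relex(sprintf("ragged embedding line (expected %d values): '%s'",
                       dim, body[which(lens != dim + 1)[1]]),
               "relex_format_error")
  }
  words <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(words)) {
    warning("duplicate words in embedding file; keeping last occurrence")
    keep <- !duplicated(words, fromLast = TRUE)
    parts <- parts[keep]
    words <- words[keep]
  }
  vecs <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(vecs) <- words
  structure(
    list(dimension = dim, vectors = vecs, unk_vector = numeric(dim)),
    class = "relex_embeddings"
  )
}

#' Look up embedding vectors
#'
#' @param table A `relex_embeddings`.
#' @param words Character vector of words.
#' @return A matrix with one row per word; unknown words get `unk_vector`.
#' @export
emb_lookup <- function(table, words) {
  i <- match(words, rownames(table$vectors))
  out <- matrix(rep(table$unk_vector, length(words)),
                nrow = length(words), byrow = TRUE)
  hit <- !is.na(i)
  if (any(hit)) out[hit, ] <- table$vectors[i[hit], , drop = FALSE]
  rownames(out) <- words
  out
}

#' Load Brown-cluster paths
#'
#' Reads a Percy-Liang-style paths file with one `bit-string TAB word TAB
#' count` entry per line. Bit strings must be non-empty sequences over
#' `{0,1}`; duplicate words resolve last-wins with a warning.
#'
#' @param content A single string with the file content, or a path to a file.
#' @return An object of class `relex_brown`: a named character vector mapping
#'   word to bit-string.
#' @export
load_brown_paths <- function(content) {
  lines <- read_resource_lines(content)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop_relex("malformed Brown paths line (expected bits TAB word TAB count)",
               "relex_format_error")
  }
  bits <- vapply(parts, `[[`, character(1), 1)
  words <- vapply(parts, `[[`, character(1), 2)
  if (any(!grepl("^[01]+$", bits))) {
    stop_relex("Brown path bit-string must be a non-empty string over {0,1}",
               "relex_format_error")
  }
  if (anyDuplicated(words)) {
    warning("duplicate words in Brown paths file; keeping last occurrence")
    keep <- !duplicated(words, fromLast = TRUE)
    bits <- bits[keep]
    words <- words[keep]
  }
  structure(stats::setNames(bits, words), class = "relex_brown")
}

#' Dictionary-backed semantic tagger
#'
#' A pluggable interface mapping a word to a set of semantic-type strings,
#' backed by a two-column dictionary (word TAB type, one pair per line or a
#' data frame). This plays the role of an external concept normalizer at
#' feature-extraction time; any tagger implementing `tag_words()` can be
#' substituted.
#'
#' @param dict A data frame with columns `word` and `type`, or a path to a
#'   TSV file with those two columns (no header).
#' @return An object of class `relex_tagger`.
#' @export
dict_tagger <- function(dict) {
  if (is.character(dict) && length(dict) == 1) {
    dict <- utils::read.delim(dict, header = FALSE,
                              col.names = c("word", "type"),
                              stringsAsFactors = FALSE)
  }
  if (!all(c("word", "type") %in% names(dict))) {
    stop_relex("tagger dictionary needs 'word' and 'type' columns",
               "relex_format_error")
  }
  map <- split(as.character(dict$type), tolower(dict$word))
  structure(list(map = map), class = "relex_tagger")
}

#' @rdname dict_tagger
#' @param tagger A `relex_tagger`.
#' @param words Character vector of words.
#' @return `tag_words()` returns a list of character vectors of semantic
#'   types (empty for unknown words).
#' @export
tag_words <- function(tagger, words) {
  out <- tagger$map[tolower(words)]
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  names(out) <- words
  out
}

#' @keywords internal
read_resource_lines <- function(content) {
  if (length(content) == 1 && !grepl("\n", content, fixed = TRUE) &&
      file.exists(content)) {
    readLines(content, warn = FALSE)
  } else {
    strsplit(paste(content, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
}
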