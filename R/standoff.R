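#' Read a standoff-annotated document
#'
#' Parses BRAT-style standoff annotation: `T` lines carry entity mentions as
#' `id TAB type start end TAB text` (character offsets 0-based,
#' end-exclusive), `R` lines carry relations as
#' `id TAB type Arg1:Tx Arg2:Ty`. Space-separated variants of the same layout
#' are accepted. Mentions are aligned to tokens by character overlap; relation
#' arguments are ordered by document position regardless of their `Arg` slot,
#' since the relation label, not argument order, carries the semantics.
#'
#' @param text_content The note text.
#' @param ann_content The annotation file content (may be empty).
#' @param doc_id Identifier for the resulting document.
#' @return A validated [relex_document()].
#' @examples
#' txt <- system.file("extdata", "example_note.txt", package = "clinrelex")
#' ann <- system.file("extdata", "example_note.ann", package = "clinrelex")
#' doc <- read_standoff(paste(readLines(txt), collapse = "\n"),
#'                      paste(readLines(ann), collapse = "\n"))
#' doc$relations
#' @export
read_standoff <- function(text_content, ann_content, doc_id = "doc") {
  tokens <- tokenize(text_content)
  n_char <- nchar(text_content)
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]

  t_lines <- lines[startsWith(lines, "T")]
  r_lines <- lines[startsWith(lines, "R")]
  other <- setdiff(lines, c(t_lines, r_lines))
  if (length(other) > 0) {
    stop_relex(sprintf("unrecognized annotation line: '%s'", other[1]),
               "relex_parse_error")
  }

  parse_t <- function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      id <- parts[1]
      mid <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
      text <- if (length(parts) >= 3) parts[3] else ""
    } else {
      ws <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      if (length(ws) < 4) {
        stop_relex(sprintf("malformed T line: '%s'", line), "relex_parse_error")
      }
      id <- ws[1]
      mid <- ws[2:4]
      text <- if (length(ws) > 4) paste(ws[-(1:4)], collapse = " ") else ""
    }
    if (length(mid) != 3) {
      stop_relex(sprintf("malformed T line: '%s'", line), "relex_parse_error")
    }
    etype <- mid[1]
    s <- suppressWarnings(as.integer(mid[2]))
    e <- suppressWarnings(as.integer(mid[3]))
    if (is.na(s) || is.na(e) || s >= e) {
      stop_relex(sprintf("bad offsets in T line: '%s'", line), "relex_parse_error")
    }
    if (s < 0 || e > n_char) {
      stop_relex(sprintf("offset outside text in T line: '%s'", line),
                 "relex_parse_error")
    }
    if (!etype %in% ENTITY_TYPES) {
      stop_relex(sprintf("unknown entity type in T line: '%s'", line),
                 "relex_parse_error")
    }
    list(id = id, etype = etype, start = s, end = e, text = text)
  }

  parse_r <- function(line) {
    parts <- strsplit(trimws(gsub("\t", " ", line)), "[[:space:]]+")[[1]]
    if (length(parts) < 4) {
      stop_relex(sprintf("malformed R line: '%s'", line), "relex_parse_error")
    }
    args <- grep("^Arg[12]:", parts[3:4], value = TRUE)
    if (length(args) != 2) {
      stop_relex(sprintf("malformed R line arguments: '%s'", line),
                 "relex_parse_error")
    }
    rtype <- parts[2]
    if (!rtype %in% RELATION_TYPES) {
      stop_relex(sprintf("unknown relation type in R line: '%s'", line),
                 "relex_parse_error")
    }
    list(id = parts[1], label = rtype,
         a1 = sub("^Arg1:", "", grep("^Arg1:", args, value = TRUE)),
         a2 = sub("^Arg2:", "", grep("^Arg2:", args, value = TRUE)))
  }

  ts <- lapply(t_lines, parse_t)
  mentions <- data.frame(
    id = vapply(ts, `[[`, character(1), "id"),
    etype = vapply(ts, `[[`, character(1), "etype"),
    first_token = integer(length(ts)),
    last_token = integer(length(ts)),
    text = vapply(ts, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(ts)) {
    s <- ts[[i]]$start
    e <- ts[[i]]$end
    hit <- which(tokens$char_start < e & tokens$char_end > s)
    if (length(hit) == 0) {
      stop_relex(sprintf("T line spans no token: '%s'", t_lines[i]),
                 "relex_parse_error")
    }
    mentions$first_token[i] <- tokens$token_index[min(hit)]
    mentions$last_token[i] <- tokens$token_index[max(hit)]
    if (!nzchar(mentions$text[i])) {
      mentions$text[i] <- substr(text_content, s + 1, e)
    }
  }

  rs <- lapply(r_lines, parse_r)
  relations <- data.frame(
    id = vapply(rs, `[[`, character(1), "id") %||% character(),
    label = vapply(rs, `[[`, character(1), "label") %||% character(),
    left_id = character(length(rs)),
    right_id = character(length(rs)),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(rs)) {
    for (a in c(rs[[i]]$a1, rs[[i]]$a2)) {
      if (!a %in% mentions$id) {
        stop_relex(sprintf("R line '%s' references missing mention '%s'",
                           r_lines[i], a), "relex_dangling_argument_error")
      }
    }
    doc_stub <- structure(list(mentions = mentions, doc_id = doc_id),
                          class = "relex_document")
    lr <- order_pair(doc_stub, rs[[i]]$a1, rs[[i]]$a2)
    relations$left_id[i] <- lr[1]
    relations$right_id[i] <- lr[2]
  }

  relex_document(doc_id, text_content, tokens, mentions, relations)
}

#' Write a document to standoff format
#'
#' Inverse of [read_standoff()]: emits the raw text plus tab-separated `T`
#' and `R` annotation lines with 0-based, end-exclusive character offsets
#' recovered from token spans. Round-trips: reading the output reproduces the
#' document.
#'
#' @param doc A validated `relex_document`.
#' @return A list with elements `text` and `ann` (single strings).
#' @export
write_standoff <- function(doc) {
  validate_document(doc)
  if (nrow(doc$mentions) > 0 && any(grepl("\n", doc$mentions$text, fixed = TRUE))) {
    stop_relex("mention text contains a newline", "relex_validation_error")
  }
  tk <- doc$tokens
  t_lines <- character(nrow(doc$mentions))
  for (i in seq_len(nrow(doc$mentions))) {
    m <- doc$mentions[i, ]
    s <- tk$char_start[match(m$first_token, tk$token_index)]
    e <- tk$char_end[match(m$last_token, tk$token_index)]
    t_lines[i] <- sprintf("%s\t%s %d %d\t%s", m$id, m$etype, s, e, m$text)
  }
  r_lines <- character(nrow(doc$relations))
  for (i in seq_len(nrow(doc$relations))) {
    r <- doc$relations[i, ]
    r_lines[i] <- sprintf("%s\t%s Arg1:%s Arg2:%s", r$id, r$label,
                          r$left_id, r$right_id)
  }
  list(text = doc$text,
       ann = paste(c(t_lines, r_lines), collapse = "\n"))
}

#' Read and write standoff document pairs on disk
#'
#' `write_corpus()` lays a split corpus out as `train/`, `dev/`, `test/`
#' directories of `<doc_id>.txt` / `<doc_id>.ann` pairs; `read_corpus()`
#' reads such a directory back.
#'
#' @param corpus A list with `train`, `dev`, `test` document lists.
#' @param dir Target directory.
#' @return `read_corpus()` returns a corpus list; `write_corpus()` returns
#'   `dir` invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  for (split in names(corpus)) {
    d <- file.path(dir, split)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (doc in corpus[[split]]) {
      so <- write_standoff(doc)
      writeLines(so$text, file.path(d, paste0(doc$doc_id, ".txt")), sep = "")
      writeLines(so$ann, file.path(d, paste0(doc$doc_id, ".ann")), sep = "")
    }
  }
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  out <- list()
  for (split in c("train", "dev", "test")) {
    d <- file.path(dir, split)
    if (!dir.exists(d)) next
    txts <- sort(list.files(d, pattern = "\\.txt$", full.names = TRUE))
    out[[split]] <- lapply(txts, function(f) {
      ann <- sub("\\.txt$", ".ann", f)
      read_standoff(
        paste(readLines(f, warn = FALSE), collapse = "\n"),
        if (file.exists(ann)) paste(readLines(ann, warn = FALSE), collapse = "\n") else "",
        doc_id = sub("\\.txt$", "", basename(f))
      )
    })
  }
  out
}
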