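#' Fit TF-IDF statistics on the training split
#'
#' Computes document frequencies over the training documents only, for word
#' n-grams (default 1-3, over lowercased token surfaces) and character
#' n-grams (default 2-3, over lowercased mention strings). The inverse
#' document frequency is `idf(t) = ln(N / df(t))` with `N` the number of
#' training documents and no smoothing; term frequency at feature-extraction
#' time is the raw count in the extracted context. Terms unseen in training
#' are dropped at apply time, so development and test content can never
#' extend the vocabulary.
#'
#' @param train_docs List of training `relex_document` objects.
#' @param word_ngrams Word n-gram orders.
#' @param char_ngrams Character n-gram orders.
#' @return An object of class `relex_tfidf` with `n_docs`, `word_idf` and
#'   `char_idf` (named numeric vectors).
#' @export
fit_tfidf <- function(train_docs, word_ngrams = 1:3, char_ngrams = 2:3) {
  if (length(train_docs) == 0) {
    stop_relex("cannot fit TF-IDF on an empty corpus", "relex_fit_error")
  }
  n <- length(train_docs)
  word_df <- new.env(parent = emptyenv())
  char_df <- new.env(parent = emptyenv())
  bump <- function(env, terms) {
    for (t in unique(terms)) {
      env[[t]] <- (env[[t]] %||% 0L) + 1L
    }
  }
  for (doc in train_docs) {
    toks <- tolower(doc$tokens$surface)
    grams <- unlist(lapply(word_ngrams, function(k) word_ngram_set(toks, k)))
    bump(word_df, grams)
    if (nrow(doc$mentions) > 0) {
      cg <- unlist(lapply(tolower(doc$mentions$text), function(s) {
        unlist(lapply(char_ngrams, function(k) char_ngram_set(s, k)))
      }))
      bump(char_df, cg)
    }
  }
  env_to_idf <- function(env) {
    df <- unlist(as.list(env))
    if (length(df) == 0) return(stats::setNames(numeric(0), character(0)))
    log(n / df)
  }
  structure(
    list(n_docs = n, word_idf = env_to_idf(word_df),
         char_idf = env_to_idf(char_df),
         word_ngrams = word_ngrams, char_ngrams = char_ngrams),
    class = "relex_tfidf"
  )
}

#' @keywords internal
word_ngram_set <- function(tokens, k) {
  n <- length(tokens)
  if (n < k) return(character(0))
  if (k == 1) return(tokens)
  out <- tokens[1:(n - k + 1)]
  for (j in 2:k) out <- paste(out, tokens[j:(n - k + j)], sep = "_")
  out
}

#' @keywords internal
char_ngram_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

#' TF-IDF weights for a bag of terms
#'
#' @param stats A fitted `relex_tfidf`.
#' @param terms Character vector of terms (with repetition; raw counts are
#'   the term frequencies).
#' @param type `"word"` or `"char"` vocabulary.
#' @return Named numeric vector of `tf * idf` weights; unseen terms dropped.
#' @export
tfidf_weights <- function(stats, terms, type = c("word", "char")) {
  type <- match.arg(type)
  idf <- if (type == "word") stats$word_idf else stats$char_idf
  if (length(terms) == 0) return(stats::setNames(numeric(0), character(0)))
  tf <- table(terms)
  hit <- names(tf)[names(tf) %in% names(idf)]
  w <- as.numeric(tf[hit]) * idf[hit]
  w[w != 0]
}
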