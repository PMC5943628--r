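#' Bundle fitted feature resources for the SVM pipeline
#'
#' Holds everything feature extraction needs: TF-IDF statistics fitted on the
#' training split, and optionally an embedding table, Brown-cluster paths, a
#' word-vector-class map and a semantic tagger. Resources are frozen after
#' fitting; applying them to new documents never updates them.
#'
#' @param tfidf A fitted [fit_tfidf()] object.
#' @param embeddings Optional `relex_embeddings`.
#' @param brown Optional `relex_brown` paths.
#' @param wvc Optional named integer word-to-cluster map from
#'   [compute_wvc()].
#' @param tagger Optional `relex_tagger`.
#' @param window Context window size in tokens on each side of a mention
#'   (default 10).
#' @return An object of class `relex_resources`.
#' @export
feature_resources <- function(tfidf, embeddings = NULL, brown = NULL,
                              wvc = NULL, tagger = NULL, window = 10) {
  stopifnot(inherits(tfidf, "relex_tfidf"))
  structure(
    list(tfidf = tfidf, embeddings = embeddings, brown = brown, wvc = wvc,
         tagger = tagger, window = window),
    class = "relex_resources"
  )
}

#' Fit all feature resources on a training split
#'
#' @param train_docs Training documents.
#' @param embeddings,brown,tagger Optional resource objects; when embeddings
#'   are given, word vector classes are derived from them by k-means.
#' @param wvc_k Number of word-vector classes (default 300, reduced with a
#'   warning when the vocabulary is smaller).
#' @param window Context window size.
#' @param seed Seed for the k-means clustering.
#' @return A `relex_resources`.
#' @export
fit_feature_resources <- function(train_docs, embeddings = NULL, brown = NULL,
                                  tagger = NULL, wvc_k = 300, window = 10,
                                  seed = 1) {
  tfidf <- fit_tfidf(train_docs)
  wvc <- if (!is.null(embeddings)) compute_wvc(embeddings, k = wvc_k, seed = seed)
  feature_resources(tfidf, embeddings = embeddings, brown = brown,
                    wvc = wvc, tagger = tagger, window = window)
}

#' Word Vector Classes: k-means clusters of embedding vectors
#'
#' Clusters the embedding vocabulary into `k` groups with standard k-means
#' (Euclidean distance) under a fixed seed; the cluster id of a word is then
#' usable as a discrete word-representation feature.
#'
#' @param embeddings A `relex_embeddings`.
#' @param k Number of clusters (default 300); reduced with a warning if the
#'   vocabulary is smaller.
#' @param seed Integer seed.
#' @return Named integer vector mapping word to cluster id in `[0, k)`.
#' @export
compute_wvc <- function(embeddings, k = 300, seed = 1) {
  v <- embeddings$vectors
  if (nrow(v) <= k) {
    if (nrow(v) < k) {
      warning(sprintf("vocabulary size %d < k = %d; reducing k", nrow(v), k))
    }
    # one word per cluster: k-means is the identity partition
    return(stats::setNames(seq_len(nrow(v)) - 1L, rownames(v)))
  }
  km <- with_seed(seed, stats::kmeans(v, centers = k, nstart = 1,
                                      iter.max = 100))
  stats::setNames(as.integer(km$cluster) - 1L, rownames(v))
}

#' Brown-cluster bit-string prefixes of a word
#'
#' Returns the hierarchical cluster prefixes of the requested lengths (the
#' full bit-string when it is shorter than a requested length); a word absent
#' from the paths yields no features.
#'
#' @param word A single word.
#' @param paths A `relex_brown`.
#' @param lengths Prefix lengths (default 4, 6, 10, 20).
#' @return Character vector of unique prefixes (possibly empty).
#' @export
brown_prefixes <- function(word, paths, lengths = c(4, 6, 10, 20)) {
  bits <- unname(unclass(paths)[word])
  if (is.na(bits)) return(character(0))
  unique(vapply(lengths, function(l) substr(bits, 1, l), character(1)))
}

#' @keywords internal
context_tokens <- function(doc, mention, window) {
  toks <- doc$tokens$surface
  first <- mention$first_token + 1L # to 1-based
  last <- mention$last_token + 1L
  left <- toks[seq(max(1, first - window), length.out = min(window, first - 1))]
  right_start <- last + 1L
  right <- if (right_start <= length(toks)) {
    toks[seq(right_start, min(length(toks), last + window))]
  } else character(0)
  c(left, right)
}

#' Extract the sparse feature vector of a candidate example
#'
#' Builds the union of namespaced feature families:
#' \describe{
#'   \item{doc:}{frequency of each entity string and entity type of the pair
#'     within the document.}
#'   \item{rel:}{token distance and number of mentions between the pair
#'     (numeric); TF-IDF-weighted word 1/2/3-grams between the pair and in a
#'     window around each mention.}
#'   \item{ent:}{one-hot left and right entity type; TF-IDF-weighted
#'     character 2/3-grams of each mention string.}
#'   \item{sem:}{semantic-type tags of mention and context tokens from the
#'     pluggable tagger.}
#'   \item{wr:}{Brown-cluster prefixes and word-vector-class ids of mention
#'     and context tokens, plus the mean embedding vector of each mention's
#'     tokens as dense dimensions.}
#' }
#' Families whose resource is absent are skipped. The result stores no
#' zero-valued entries and extraction is a pure function of its inputs.
#'
#' @param example One row of a `relex_dataset`.
#' @param doc The `relex_document` the example lives in.
#' @param resources A fitted `relex_resources`.
#' @return Named numeric vector (sparse feature representation).
#' @export
extract_features <- function(example, doc, resources) {
  stopifnot(inherits(resources, "relex_resources"))
  w <- resources$window
  l <- mention_row(doc, example$left_id)
  r <- mention_row(doc, example$right_id)
  toks_lower <- tolower(doc$tokens$surface)
  feats <- list()
  add <- function(names, values) {
    keep <- values != 0
    if (any(keep)) feats[[length(feats) + 1]] <<- stats::setNames(values[keep], names[keep])
  }

  # doc: entity string and entity type frequencies in the document
  mtexts <- tolower(doc$mentions$text)
  for (m in list(l, r)) {
    add(paste0("doc:ent=", tolower(m$text)), sum(mtexts == tolower(m$text)))
    add(paste0("doc:etype=", m$etype), sum(doc$mentions$etype == m$etype))
  }

  # rel: distance, mentions between, n-grams between and around
  add("rel:distance", token_distance(doc, example$left_id, example$right_id))
  add("rel:between", mentions_between(doc, example$left_id, example$right_id))
  gap_idx <- seq(l$last_token + 2L, length.out =
                   max(0L, r$first_token - l$last_token - 1L))
  gap <- toks_lower[gap_idx]
  grams <- unlist(lapply(resources$tfidf$word_ngrams,
                         function(k) word_ngram_set(gap, k)))
  tw <- tfidf_weights(resources$tfidf, grams, "word")
  add(paste0("rel:ngram=", names(tw)), as.numeric(tw))
  ctx <- c(tolower(context_tokens(doc, l, w)), tolower(context_tokens(doc, r, w)))
  cgrams <- unlist(lapply(resources$tfidf$word_ngrams,
                          function(k) word_ngram_set(ctx, k)))
  cw <- tfidf_weights(resources$tfidf, cgrams, "word")
  add(paste0("rel:ctx=", names(cw)), as.numeric(cw))

  # ent: one-hot types, character n-grams of the mention strings
  add(paste0("ent:ltype=", l$etype), 1)
  add(paste0("ent:rtype=", r$etype), 1)
  for (side in c("l", "r")) {
    m <- if (side == "l") l else r
    ch <- unlist(lapply(resources$tfidf$char_ngrams,
                        function(k) char_ngram_set(tolower(m$text), k)))
    chw <- tfidf_weights(resources$tfidf, ch, "char")
    add(paste0("ent:", side, "char=", names(chw)), as.numeric(chw))
  }

  # sem: semantic types of mention + context tokens
  if (!is.null(resources$tagger)) {
    mention_toks <- tolower(unlist(strsplit(c(l$text, r$text), " ", fixed = TRUE)))
    tags <- unlist(tag_words(resources$tagger, c(mention_toks, ctx)))
    if (length(tags) > 0) {
      tt <- table(tags)
      add(paste0("sem:", names(tt)), as.numeric(tt))
    }
  }

  # wr: Brown prefixes, word vector classes, mean mention embeddings
  wr_toks <- unique(c(tolower(unlist(strsplit(c(l$text, r$text), " ", fixed = TRUE))), ctx))
  if (!is.null(resources$brown)) {
    pref <- unlist(lapply(wr_toks, brown_prefixes, paths = resources$brown))
    if (length(pref) > 0) {
      pt <- table(pref)
      add(paste0("wr:brown=", names(pt)), as.numeric(pt))
    }
  }
  if (!is.null(resources$wvc)) {
    ids <- resources$wvc[wr_toks]
    ids <- ids[!is.na(ids)]
    if (length(ids) > 0) {
      it <- table(ids)
      add(paste0("wr:wvc=", names(it)), as.numeric(it))
    }
  }
  if (!is.null(resources$embeddings)) {
    for (side in c("l", "r")) {
      m <- if (side == "l") l else r
      mt <- tolower(unlist(strsplit(m$text, " ", fixed = TRUE)))
      v <- colMeans(emb_lookup(resources$embeddings, mt))
      add(sprintf("wr:emb%s:%03d", side, seq_along(v)), v)
    }
  }

  out <- unlist(feats)
  if (is.null(out)) out <- stats::setNames(numeric(0), character(0))
  # merge duplicated feature names by summation
  if (anyDuplicated(names(out))) {
    out <- tapply(out, names(out), sum)
    out <- stats::setNames(as.numeric(out), names(out))
    out <- out[out != 0]
  }
  out
}

#' Build a sparse design matrix for a dataset
#'
#' Extracts features for every example and assembles a `dgCMatrix`. When
#' `vocab` is `NULL` (training), the feature vocabulary is the set of
#' feature names observed; otherwise features outside `vocab` are dropped,
#' so applying a fitted pipeline to new data introduces no new columns.
#'
#' @param dataset A `relex_dataset`.
#' @param docs Named document list from [doc_index()].
#' @param resources A fitted `relex_resources`.
#' @param vocab Optional fixed feature vocabulary (character vector).
#' @return List with `matrix` (examples x features) and `vocab`.
#' @export
build_feature_matrix <- function(dataset, docs, resources, vocab = NULL) {
  n <- nrow(dataset)
  fl <- vector("list", n)
  for (i in seq_len(n)) {
    fl[[i]] <- extract_features(dataset[i, ], docs[[dataset$doc_id[i]]],
                                resources)
  }
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(lapply(fl, names))))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    j <- match(names(fl[[i]]), vocab)
    keep <- !is.na(j)
    ii <- c(ii, rep.int(i, sum(keep)))
    jj <- c(jj, j[keep])
    xx <- c(xx, as.numeric(fl[[i]])[keep])
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, length(vocab)),
                            dimnames = list(NULL, vocab))
  list(matrix = m, vocab = vocab)
}
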