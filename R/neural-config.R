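#' Configuration of the neural relation extractors
#'
#' Collects the architecture and training hyperparameters of the
#' LSTM/BiLSTM relation classifiers: hidden size `k`, context window size
#' `L`, embedding dimension, the bidirectional / attention / augmented-feature
#' switches, dropout rates on the LSTM input and output vectors, l2
#' regularization strength, and the ADAM optimization settings. Defaults
#' follow the reference training recipe: `k = 100`, `L = 30`, 300-dimensional
#' embeddings, 20% input and 30% output dropout, l2 strength `1e-3`, and 30
#' epochs for unidirectional models versus 60 for bidirectional or
#' attentional ones.
#'
#' @param hidden LSTM hidden size `k`.
#' @param window Context window size `L` (tokens, ending at the mention head).
#' @param emb_dim Word-embedding dimension.
#' @param bidirectional Concatenate forward and backward encoder outputs
#'   (doubling attention and MLP input widths).
#' @param attention Use global attention over the window outputs.
#' @param augmented Append embedded token-distance, mention-distance and
#'   mention-type features to the MLP input.
#' @param dropout_in,dropout_out Dropout rates on LSTM input / output
#'   vectors, applied during training only.
#' @param l2 l2 regularization strength on weight matrices.
#' @param lr ADAM learning rate (default moments are used).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs; `NULL` selects 30 (unidirectional, no
#'   attention) or 60 (bidirectional or attentional).
#' @param feat_dim Embedding dimension of each augmented feature.
#' @param train_embeddings Update word embeddings during training; `NULL`
#'   trains them when no pretrained table is supplied and freezes them
#'   otherwise.
#' @param seed Integer seed governing initialization, dropout and batch
#'   order.
#' @return An object of class `relex_neural_config`.
#' @export
neural_config <- function(hidden = 100, window = 30, emb_dim = 300,
                          bidirectional = FALSE, attention = FALSE,
                          augmented = FALSE, dropout_in = 0.2,
                          dropout_out = 0.3, l2 = 1e-3, lr = 1e-3,
                          batch_size = 32, epochs = NULL, feat_dim = 16,
                          train_embeddings = NULL, seed = 1) {
  if (hidden < 1 || window < 1 || emb_dim < 1) {
    stop_relex("hidden size, window size and embedding dimension must be positive",
               "relex_config_error")
  }
  if (dropout_in < 0 || dropout_in >= 1 || dropout_out < 0 || dropout_out >= 1) {
    stop_relex("dropout rates must lie in [0, 1)", "relex_config_error")
  }
  if (is.null(epochs)) {
    epochs <- if (bidirectional || attention) 60 else 30
  }
  structure(
    list(hidden = hidden, window = window, emb_dim = emb_dim,
         bidirectional = bidirectional, attention = attention,
         augmented = augmented, dropout_in = dropout_in,
         dropout_out = dropout_out, l2 = l2, lr = lr,
         batch_size = batch_size, epochs = epochs, feat_dim = feat_dim,
         train_embeddings = train_embeddings, seed = seed),
    class = "relex_neural_config"
  )
}

# Model choice shorthands used by the orchestration layer and CLI.
neural_config_for <- function(model, ...) {
  base <- switch(model,
    "lstm" = list(),
    "bilstm" = list(bidirectional = TRUE),
    "lstm-att" = list(attention = TRUE),
    "bilstm-att" = list(bidirectional = TRUE, attention = TRUE),
    "bilstm-att-feat" = list(bidirectional = TRUE, attention = TRUE,
                             augmented = TRUE),
    stop_relex(sprintf("unknown neural model '%s'", model),
               "relex_config_error")
  )
  do.call(neural_config, utils::modifyList(base, list(...)))
}

#' Build the token vocabulary of the neural models
#'
#' Lowercased surface vocabulary of the training documents, with reserved
#' `<pad>` (index 1, zero embedding) and `<unk>` (index 2) entries.
#'
#' @param docs Training documents.
#' @return Character vector; the vocabulary with reserved symbols first.
#' @export
build_vocab <- function(docs) {
  words <- sort(unique(unlist(lapply(docs, function(d) tolower(d$tokens$surface)))))
  c("<pad>", "<unk>", words)
}

# Distance buckets for the augmented feature embeddings:
# 0, 1, 2, 3-4, 5-8, 9-16, 17-32, 33-100, >100.
distance_bucket <- function(d) {
  findInterval(pmin(d, 101L), c(0, 1, 2, 3, 5, 9, 17, 33, 101)) # 1..9
}

#' Encode a dataset for the neural models
#'
#' For each example, extracts the two entity windows: the `L` tokens ending
#' at each mention's head token (its last token), left-padded with `<pad>`
#' at the document start, mapped to vocabulary indices with `<unk>` for
#' out-of-vocabulary tokens. Also computes the bucketed token distance,
#' bucketed mention-between count, and the entity-type indices used by the
#' augmented variant.
#'
#' @param dataset A `relex_dataset`.
#' @param docs Named document list.
#' @param vocab Vocabulary from [build_vocab()].
#' @param window Window size `L`.
#' @return A list of encoded arrays (`ids_l`, `ids_r` are `L x N`).
#' @export
encode_examples <- function(dataset, docs, vocab, window) {
  n <- nrow(dataset)
  ids_l <- matrix(1L, nrow = window, ncol = n)
  ids_r <- matrix(1L, nrow = window, ncol = n)
  dist_b <- integer(n)
  ment_b <- integer(n)
  ltype <- integer(n)
  rtype <- integer(n)
  for (i in seq_len(n)) {
    doc <- docs[[dataset$doc_id[i]]]
    l <- mention_row(doc, dataset$left_id[i])
    r <- mention_row(doc, dataset$right_id[i])
    toks <- tolower(doc$tokens$surface)
    for (side in 1:2) {
      m <- if (side == 1) l else r
      head <- m$last_token + 1L # 1-based position of the head token
      pos <- seq(head - window + 1L, head)
      ids <- rep(1L, window)
      inside <- pos >= 1
      idx <- match(toks[pos[inside]], vocab)
      idx[is.na(idx)] <- 2L
      ids[inside] <- idx
      if (side == 1) ids_l[, i] <- ids else ids_r[, i] <- ids
    }
    dist_b[i] <- distance_bucket(token_distance(doc, l$id, r$id))
    ment_b[i] <- distance_bucket(mentions_between(doc, l$id, r$id))
    ltype[i] <- match(l$etype, ENTITY_TYPES)
    rtype[i] <- match(r$etype, ENTITY_TYPES)
  }
  list(ids_l = ids_l, ids_r = ids_r, dist_b = dist_b, ment_b = ment_b,
       ltype = ltype, rtype = rtype, labels = dataset$label)
}

#' Initialize neural model parameters
#'
#' Uniform Glorot initialization for all weight matrices; biases start at 0
#' except the LSTM forget-gate bias, which starts at 1 to ease early gradient
#' flow. Each entity side has its own LSTM encoder (and attention block); the
#' word-to-input projection layer is shared across both encoders. The `<pad>`
#' embedding row is fixed at zero.
#'
#' @param config A `relex_neural_config`.
#' @param vocab_size Vocabulary size (including reserved symbols).
#' @param n_classes Number of output classes.
#' @param pretrained Optional `relex_embeddings` to seed (and by default
#'   freeze) the embedding table; its dimension must equal `emb_dim`.
#' @param vocab The vocabulary (needed to align pretrained vectors).
#' @return Nested parameter list of class `relex_neural_params`.
#' @export
init_neural_params <- function(config, vocab_size, n_classes,
                               pretrained = NULL, vocab = NULL) {
  k <- config$hidden
  e <- config$emb_dim
  m <- k * (1 + config$bidirectional)
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  lstm_block <- function() {
    b <- numeric(4 * k)
    b[(2 * k + 1):(3 * k)] <- 1 # forget gate bias
    list(Wx = glorot(4 * k, k), Wh = glorot(4 * k, k), b = b)
  }
  att_block <- function() {
    list(W1 = glorot(m, m), W2 = glorot(m, m), W3 = glorot(m, m),
         W4 = glorot(m, m), w = as.numeric(glorot(m, 1)))
  }
  emb <- glorot(vocab_size, e) * 0.5
  emb[1, ] <- 0
  if (!is.null(pretrained)) {
    if (pretrained$dimension != e) {
      stop_relex("pretrained embedding dimension does not match config",
                 "relex_config_error")
    }
    if (is.null(vocab)) {
      stop_relex("vocab required to align pretrained embeddings",
                 "relex_config_error")
    }
    hit <- match(vocab, rownames(pretrained$vectors))
    ok <- which(!is.na(hit))
    emb[ok, ] <- pretrained$vectors[hit[ok], , drop = FALSE]
    emb[1, ] <- 0
  }
  params <- list(
    emb = emb,
    W_in = glorot(k, e),
    b_in = numeric(k),
    enc_l = list(fwd = lstm_block()),
    enc_r = list(fwd = lstm_block()),
    mlp = list(
      W = glorot(n_classes, 2 * m + if (config$augmented) 4 * config$feat_dim else 0),
      b = numeric(n_classes),
      Ws = glorot(n_classes, n_classes),
      bs = numeric(n_classes)
    )
  )
  if (config$bidirectional) {
    params$enc_l$bwd <- lstm_block()
    params$enc_r$bwd <- lstm_block()
  }
  if (config$attention) {
    params$att_l <- att_block()
    params$att_r <- att_block()
  }
  if (config$augmented) {
    f <- config$feat_dim
    params$feat <- list(
      dist = glorot(9, f), ment = glorot(9, f),
      type = glorot(length(ENTITY_TYPES), f)
    )
  }
  class(params) <- "relex_neural_params"
  params
}

#' Expose a packed LSTM block as the eight gate matrices
#'
#' Splits the packed parameterization used by the batched trainer into the
#' gate-level form `W1..W8`, `b1..b4` consumed by [lstm_step()]: `W1/W2/b1`
#' for the input gate, `W3/W4/b2` for the candidate, `W5/W6/b3` for the
#' forget gate, `W7/W8/b4` for the output gate.
#'
#' @param block A packed LSTM block (`Wx`, `Wh`, `b`).
#' @return List with `W1`..`W8` and `b1`..`b4`.
#' @export
lstm_block_to_eq <- function(block) {
  k <- length(block$b) / 4
  rows <- function(j) ((j - 1) * k + 1):(j * k)
  list(
    W1 = block$Wx[rows(1), , drop = FALSE], W2 = block$Wh[rows(1), , drop = FALSE],
    b1 = block$b[rows(1)],
    W3 = block$Wx[rows(2), , drop = FALSE], W4 = block$Wh[rows(2), , drop = FALSE],
    b2 = block$b[rows(2)],
    W5 = block$Wx[rows(3), , drop = FALSE], W6 = block$Wh[rows(3), , drop = FALSE],
    b3 = block$b[rows(3)],
    W7 = block$Wx[rows(4), , drop = FALSE], W8 = block$Wh[rows(4), , drop = FALSE],
    b4 = block$b[rows(4)]
  )
}
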