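# Shared fixtures, built in code at test time.

# A hand-laid-out document: "aspirin 20 mg po daily for severe nausea ."
# with a Medication, Dosage, Route, Frequency, Severity and ADE mention.
fixture_doc <- function() {
  text <- "aspirin 20 mg po daily for severe nausea ."
  tokens <- tokenize(text)
  mentions <- data.frame(
    id = c("T1", "T2", "T3", "T4", "T5", "T6"),
    etype = c("Medication", "Dosage", "Route", "Frequency", "Severity", "ADE"),
    first_token = c(0L, 1L, 3L, 4L, 6L, 7L),
    last_token = c(0L, 2L, 3L, 4L, 6L, 7L),
    text = c("aspirin", "20 mg", "po", "daily", "severe", "nausea"),
    stringsAsFactors = FALSE
  )
  relations <- data.frame(
    id = c("R1", "R2", "R3", "R4"),
    label = c("Dosage", "Route", "Frequency", "Severity"),
    left_id = c("T1", "T1", "T1", "T5"),
    right_id = c("T2", "T3", "T4", "T6"),
    stringsAsFactors = FALSE
  )
  relex_document("fix1", text, tokens, mentions, relations)
}

# Small deterministic corpus for pipeline tests.
fixture_corpus <- function(n_docs = 20, relations_per_doc = 8, seed = 7) {
  generate_corpus(gen_config(n_docs = n_docs,
                             relations_per_doc = relations_per_doc,
                             seed = seed))
}

# Candidate datasets + doc index for a corpus.
fixture_experiment <- function(corpus, corruptions = 2, keep_rate = 0.5,
                               seed = 1) {
  prepare_experiment(corpus, corruptions_per_side = corruptions,
                     keep_rate = keep_rate, seed = seed)
}

# A small random embedding table.
fixture_embeddings <- function(words, dim = 8, seed = 1) {
  set.seed(seed)
  vecs <- matrix(rnorm(length(words) * dim), length(words), dim)
  rownames(vecs) <- words
  structure(list(dimension = dim, vectors = vecs, unk_vector = numeric(dim)),
            class = "relex_embeddings")
}

# Random parameters + batch for neural oracle tests.
fixture_neural_batch <- function(cfg, vocab_size = 7, n_classes = 4,
                                 batch = 3, seed = 5) {
  set.seed(seed)
  params <- init_neural_params(cfg, vocab_size, n_classes)
  b <- list(
    ids_l = matrix(sample.int(vocab_size, cfg$window * batch, TRUE),
                   cfg$window, batch),
    ids_r = matrix(sample.int(vocab_size, cfg$window * batch, TRUE),
                   cfg$window, batch),
    dist_b = sample.int(9, batch, TRUE), ment_b = sample.int(9, batch, TRUE),
    ltype = sample.int(9, batch, TRUE), rtype = sample.int(9, batch, TRUE),
    y = sample.int(n_classes, batch, TRUE)
  )
  list(params = params, batch = b)
}
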