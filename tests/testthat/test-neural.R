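test_that("the LSTM step obeys its closed-form special cases", {
  k <- 3
  zero <- list(W1 = matrix(0, k, k), W2 = matrix(0, k, k),
               W3 = matrix(0, k, k), W4 = matrix(0, k, k),
               W5 = matrix(0, k, k), W6 = matrix(0, k, k),
               W7 = matrix(0, k, k), W8 = matrix(0, k, k),
               b1 = numeric(k), b2 = numeric(k), b3 = numeric(k),
               b4 = numeric(k))
  st <- lstm_step(zero, rnorm(k), numeric(k), numeric(k))
  expect_equal(st$i, rep(0.5, k))
  expect_equal(st$f, rep(0.5, k))
  expect_equal(st$o, rep(0.5, k))
  expect_equal(st$c, numeric(k))
  expect_equal(st$h, numeric(k))
  # zero weights with nonzero previous cell: c_t = 0.5 * c elementwise
  cp <- c(1, -2, 4)
  st2 <- lstm_step(zero, rnorm(k), numeric(k), cp)
  expect_equal(st2$c, 0.5 * cp)
  expect_error(lstm_step(zero, rnorm(5), numeric(k), numeric(k)),
               class = "relex_shape_error")
})

test_that("LSTM step, attention and composition match scalar oracles", {
  set.seed(101)
  for (rep in 1:5) {
    k <- 3
    p <- rand_lstm_params(k)
    x <- rnorm(k); h <- rnorm(k); c <- rnorm(k)
    got <- lstm_step(p, x, h, c)
    want <- oracle_lstm_step(p, x, h, c)
    expect_lt(max(abs(got$h - want$h)), 1e-10)
    expect_lt(max(abs(got$c - want$c)), 1e-10)
    expect_true(all(got$i > 0 & got$i < 1))
    expect_true(all(got$f > 0 & got$f < 1))
    expect_true(all(got$o > 0 & got$o < 1))

    ap <- list(W1 = matrix(rnorm(9), 3), W2 = matrix(rnorm(9), 3),
               W3 = matrix(rnorm(9), 3), W4 = matrix(rnorm(9), 3),
               w = rnorm(3))
    S <- matrix(rnorm(12), 3, 4)
    hl <- rnorm(3)
    got_a <- attend(ap, S, hl)
    want_a <- oracle_attend(ap, S, hl)
    expect_lt(max(abs(got_a$a - want_a$a)), 1e-10)
    expect_lt(max(abs(got_a$h_prime - want_a$h_prime)), 1e-10)
    expect_equal(sum(got_a$a), 1)
    expect_true(all(got_a$a > 0 & got_a$a < 1))

    cp <- list(W = matrix(rnorm(24), 4, 6), b = rnorm(4),
               Ws = matrix(rnorm(16), 4, 4), bs = rnorm(4))
    want_p <- oracle_compose(cp, c(0.3, -1, 2), c(0.5, 0.1, -0.2))
    got_p <- compose_and_classify(cp, c(0.3, -1, 2), c(0.5, 0.1, -0.2))
    expect_lt(max(abs(got_p - want_p)), 1e-10)
    expect_equal(sum(got_p), 1, tolerance = 1e-9)
  }
})

test_that("attention degenerate cases: single column and identical columns", {
  ap <- list(W1 = matrix(rnorm(9), 3), W2 = matrix(rnorm(9), 3),
             W3 = matrix(rnorm(9), 3), W4 = matrix(rnorm(9), 3), w = rnorm(3))
  S1 <- matrix(rnorm(3), 3, 1)
  got <- attend(ap, S1, S1[, 1])
  expect_equal(got$a, 1)
  expect_equal(got$z, S1[, 1])
  # identical columns: z equals that column regardless of a
  col <- rnorm(3)
  S4 <- matrix(col, 3, 4)
  got4 <- attend(ap, S4, col)
  expect_equal(got4$z, col, tolerance = 1e-12)
})

test_that("zero-weight composition yields uniform probabilities", {
  cp <- list(W = matrix(0, 4, 6), b = numeric(4),
             Ws = matrix(0, 4, 4), bs = numeric(4))
  expect_equal(compose_and_classify(cp, rnorm(3), rnorm(3)), rep(0.25, 4))
})

test_that("the packed batched forward agrees with the equation-level step", {
  cfg <- neural_config(hidden = 4, window = 3, emb_dim = 5,
                       dropout_in = 0, dropout_out = 0, seed = 2)
  set.seed(8)
  params <- init_neural_params(cfg, vocab_size = 9, n_classes = 3)
  ids <- matrix(sample.int(9, 6, TRUE), 3, 2)
  fc <- clinrelex:::encoder_forward(params, cfg, params$enc_l, NULL, ids,
                                    train = FALSE)
  eq <- lstm_block_to_eq(params$enc_l$fwd)
  for (b in 1:2) {
    h <- numeric(4); c <- numeric(4)
    for (t in 1:3) {
      x <- as.numeric(params$W_in %*% params$emb[ids[t, b], ] + params$b_in)
      st <- lstm_step(eq, x, h, c)
      h <- st$h; c <- st$c
      expect_equal(fc$fwd$H[[t]][, b], h, tolerance = 1e-12)
    }
  }
})

test_that("window encoding pads at document start and doubles width when bidirectional", {
  doc <- fixture_doc()
  vocab <- build_vocab(list(doc))
  ds <- gold_examples(list(doc))
  enc <- encode_examples(ds, doc_index(list(doc)), vocab, window = 5)
  # left window of "aspirin" (token 0): 4 pads then the head token
  expect_equal(enc$ids_l[, 1], c(1L, 1L, 1L, 1L, match("aspirin", vocab)))
  # bidirectional output width 2k
  cfg <- neural_config(hidden = 3, window = 5, emb_dim = 4,
                       bidirectional = TRUE, dropout_in = 0, dropout_out = 0)
  set.seed(1)
  params <- init_neural_params(cfg, length(vocab), 3)
  fc <- clinrelex:::encoder_forward(params, cfg, params$enc_l, NULL,
                                    enc$ids_l, train = FALSE)
  expect_equal(nrow(fc$out), 6)
  expect_error(neural_config(window = 0), class = "relex_config_error")
})

test_that("analytic gradients match numerical differentiation on a tiny network", {
  for (variant in list(list(),
                       list(bidirectional = TRUE, attention = TRUE,
                            augmented = TRUE))) {
    cfg <- do.call(neural_config,
                   c(list(hidden = 3, window = 2, emb_dim = 4, feat_dim = 3,
                          dropout_in = 0, dropout_out = 0, seed = 3), variant))
    fx <- fixture_neural_batch(cfg)
    expect_lt(gradient_check(cfg, fx$batch, fx$params, n_coords = 60, seed = 2),
              1e-4)
  }
})

test_that("training learns a separable toy problem and selects by dev macro-F1", {
  cfg <- gen_config(
    n_docs = 12, relations_per_doc = 5,
    rel_weights = c(Dosage = 1, Route = 0, Frequency = 0, Duration = 0,
                    Indication = 0, Adverse = 0, Severity = 1),
    seed = 2
  )
  corpus <- generate_corpus(cfg)
  all_docs <- c(corpus$train, corpus$dev, corpus$test)
  docs <- doc_index(all_docs)
  tr <- build_dataset(corpus$train, NULL, seed = 1)
  expect_gte(nrow(tr), 50)
  nc <- neural_config(hidden = 16, window = 5, emb_dim = 16, epochs = 30,
                      lr = 3e-3, batch_size = 8, seed = 1)
  m <- train_neural(nc, tr, tr, docs)
  expect_gte(mean(predict_neural(m, tr, docs) == tr$label), 0.95)
  # training loss decreases over the first epochs
  expect_lt(mean(m$trace$train_loss[4:6]), m$trace$train_loss[1])
  # the selected epoch maximizes the dev trace
  expect_equal(m$trace$dev_macro_f1[m$best_epoch], max(m$trace$dev_macro_f1))
  # same seed: identical training trace
  m2 <- train_neural(nc, tr, tr, docs)
  expect_identical(m$trace, m2$trace)
  # inference is deterministic
  expect_identical(predict_neural(m, tr, docs), predict_neural(m, tr, docs))
})

test_that("softmax outputs normalize and shapes stay consistent in all modes", {
  cfg <- neural_config(hidden = 3, window = 2, emb_dim = 4, feat_dim = 3,
                       bidirectional = TRUE, attention = TRUE,
                       augmented = TRUE, seed = 3)
  fx <- fixture_neural_batch(cfg)
  fw <- clinrelex:::neural_forward(fx$params, cfg, fx$batch, train = FALSE)
  expect_equal(colSums(fw$P), rep(1, 3), tolerance = 1e-9)
  att <- fw$fc_l$att
  expect_equal(colSums(att$A), rep(1, 3), tolerance = 1e-9)
  expect_equal(dim(fw$fc_l$out), c(6, 3)) # 2k wide when bidirectional
})

test_that("training aborts with a diagnostic on divergence", {
  corpus <- fixture_corpus(n_docs = 8, relations_per_doc = 4, seed = 6)
  docs <- doc_index(corpus$train)
  tr <- build_dataset(corpus$train, NULL, seed = 1)
  # an l2 strength with lr * 2 * l2 > 1 makes the decay factor explosive,
  # so the weights overflow and the loss goes non-finite within a few epochs
  nc <- neural_config(hidden = 8, window = 4, emb_dim = 8, epochs = 40,
                      batch_size = 4, lr = 1, l2 = 50, seed = 1)
  expect_error(train_neural(nc, tr, tr, docs),
               class = "relex_divergence_error")
})
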