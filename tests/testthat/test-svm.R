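test_that("TF-IDF statistics follow ln(N/df) on the training split only", {
  corpus <- fixture_corpus(n_docs = 9, relations_per_doc = 4, seed = 51)
  docs <- corpus$train # 7 docs
  stats <- fit_tfidf(docs)
  expect_equal(stats$n_docs, length(docs))
  # a unigram present in every document has idf ln(1) = 0
  in_all <- names(which(stats$word_idf == 0))
  if (length(in_all) > 0) {
    present <- vapply(docs, function(d) in_all[1] %in% tolower(d$tokens$surface),
                      logical(1))
    expect_true(all(present))
  }
  # closed form: df = 1 among 3 docs -> idf = ln(3)
  three <- fit_tfidf(docs[1:3])
  df1 <- names(three$word_idf)[abs(three$word_idf - log(3)) < 1e-12]
  expect_gt(length(df1), 0)
  expect_error(fit_tfidf(list()), class = "relex_fit_error")

  # weights: tf * idf, unseen terms dropped
  w <- tfidf_weights(three, c(df1[1], df1[1], "zzz_unseen"), "word")
  expect_equal(unname(w[df1[1]]), 2 * log(3))
  expect_false("zzz_unseen" %in% names(w))
})

test_that("applying a fitted pipeline to new data adds no vocabulary", {
  corpus <- fixture_corpus(n_docs = 12, relations_per_doc = 5, seed = 52)
  data <- fixture_experiment(corpus)
  stats1 <- fit_tfidf(corpus$train)
  res <- feature_resources(stats1, window = 10)
  fm_train <- build_feature_matrix(data$train, data$docs, res)
  fm_dev <- build_feature_matrix(data$dev, data$docs, res, fm_train$vocab)
  expect_identical(colnames(fm_dev$matrix), fm_train$vocab)
  # TF-IDF statistics are untouched by dev/test content
  stats2 <- fit_tfidf(corpus$train)
  expect_identical(stats1$word_idf, stats2$word_idf)
  expect_identical(stats1$char_idf, stats2$char_idf)
})

test_that("word vector classes cluster co-located words together", {
  words <- c(paste0("a", 1:4), paste0("b", 1:4))
  vecs <- rbind(matrix(rnorm(16, mean = 0, sd = 0.01), 4),
                matrix(rnorm(16, mean = 10, sd = 0.01), 4))
  rownames(vecs) <- words
  emb <- structure(list(dimension = 4, vectors = vecs,
                        unk_vector = numeric(4)), class = "relex_embeddings")
  wvc <- compute_wvc(emb, k = 2, seed = 1)
  expect_length(unique(wvc[1:4]), 1)
  expect_length(unique(wvc[5:8]), 1)
  expect_false(wvc[["a1"]] == wvc[["b1"]])
  # k = 1: everything in cluster 0
  expect_true(all(compute_wvc(emb, k = 1, seed = 1) == 0))
  # k larger than vocabulary: reduced with warning
  expect_warning(compute_wvc(emb, k = 100, seed = 1), "reducing k")
})

test_that("k-means objective beats random assignment on synthetic vectors", {
  emb <- fixture_embeddings(paste0("w", 1:500), dim = 6, seed = 3)
  wvc <- compute_wvc(emb, k = 20, seed = 1)
  wss <- function(assign) {
    sum(vapply(unique(assign), function(cl) {
      v <- emb$vectors[assign == cl, , drop = FALSE]
      sum(sweep(v, 2, colMeans(v))^2)
    }, numeric(1)))
  }
  set.seed(2)
  random_assign <- sample(0:19, 500, replace = TRUE)
  expect_lt(wss(wvc), wss(stats::setNames(random_assign, names(wvc))))
})

test_that("feature extraction is pure and carries the documented families", {
  doc <- fixture_doc()
  res <- feature_resources(
    fit_tfidf(list(doc)),
    brown = load_brown_paths("0010\taspirin\t5\n0111\tdaily\t3"),
    tagger = dict_tagger(data.frame(word = "aspirin", type = "pharm")),
    embeddings = fixture_embeddings(c("aspirin", "nausea", "severe")),
    window = 10
  )
  ex <- data.frame(doc_id = "fix1", left_id = "T1", right_id = "T5",
                   label = "None", provenance = "corrupted",
                   stringsAsFactors = FALSE)
  f1 <- extract_features(ex, doc, res)
  f2 <- extract_features(ex, doc, res)
  expect_identical(f1, f2)
  expect_true(all(f1 != 0))
  expect_equal(unname(f1["rel:distance"]), 5)
  expect_equal(unname(f1["rel:between"]), 3)
  expect_equal(unname(f1["ent:ltype=Medication"]), 1)
  expect_equal(unname(f1["ent:rtype=Severity"]), 1)
  expect_equal(sum(startsWith(names(f1), "ent:ltype=")), 1)
  expect_equal(sum(startsWith(names(f1), "ent:rtype=")), 1)
  expect_true(any(startsWith(names(f1), "wr:brown=0010")))
  expect_true(any(startsWith(names(f1), "sem:pharm")))
  expect_true(any(startsWith(names(f1), "wr:embl:")))
  # adjacent pair: distance 0 is not stored (sparse vectors hold no zeros)
  ex0 <- data.frame(doc_id = "fix1", left_id = "T1", right_id = "T2",
                    label = "Dosage", provenance = "gold",
                    stringsAsFactors = FALSE)
  f0 <- extract_features(ex0, doc, res)
  expect_false("rel:distance" %in% names(f0))
})

test_that("grid search selects by dev macro-F1 and refits on train+dev", {
  corpus <- fixture_corpus(n_docs = 14, relations_per_doc = 6, seed = 53)
  data <- fixture_experiment(corpus)
  res <- fit_feature_resources(corpus$train)
  model <- train_svm(data$train, data$dev, data$docs, res,
                     grid = c(0.1, 1), seed = 1)
  expect_s3_class(model, "relex_svm")
  expect_equal(nrow(model$trace), 2)
  expect_gte(model$trace$dev_macro_f1[model$trace$cost == model$cost][1],
             max(model$trace$dev_macro_f1) - 1e-12)
  # single grid point: trivially selected
  m1 <- train_svm(data$train, data$dev, data$docs, res, grid = 1, seed = 1)
  expect_equal(m1$cost, 1)
  # single-class training data is an error
  one_class <- data$train[data$train$label == "None", ]
  expect_error(train_svm(one_class, data$dev, data$docs, res, grid = 1),
               class = "relex_fit_error")
})

test_that("SVM memorizes separable training data and predicts deterministically", {
  corpus <- fixture_corpus(n_docs = 14, relations_per_doc = 6, seed = 53)
  data <- fixture_experiment(corpus)
  res <- fit_feature_resources(corpus$train)
  model <- train_svm(data$train, data$dev, data$docs, res, grid = 10, seed = 1)
  pred_train <- predict_svm(model, data$train, data$docs)
  expect_gt(mean(pred_train == data$train$label), 0.95)
  expect_identical(pred_train, predict_svm(model, data$train, data$docs))
})

test_that("SVM models persist to a plain-text directory", {
  corpus <- fixture_corpus(n_docs = 10, relations_per_doc = 5, seed = 54)
  data <- fixture_experiment(corpus)
  res <- fit_feature_resources(corpus$train)
  model <- train_svm(data$train, data$dev, data$docs, res, grid = 1, seed = 1)
  dir <- withr::local_tempdir()
  write_svm_model(model, dir)
  back <- read_svm_model(dir, res)
  expect_identical(predict_svm(back, data$test, data$docs),
                   predict_svm(model, data$test, data$docs))
})
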