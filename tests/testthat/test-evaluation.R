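test_that("metric formulas follow the TP/FP/FN definitions with 0/0 = 0", {
  gold <- c("Dosage", "Dosage", "None", "Route", "None")
  pred <- c("Dosage", "None", "Dosage", "Route", "None")
  ev <- score(gold, pred)
  per <- ev$per_class
  d <- per[per$label == "Dosage", ]
  expect_equal(d$tp, 1L)
  expect_equal(d$fp, 1L)
  expect_equal(d$fn, 1L)
  expect_equal(d$precision, 50)
  expect_equal(d$recall, 50)
  expect_equal(d$f1, 50)
  # a class never predicted nor gold: all zeros, not NaN
  sev <- per[per$label == "Severity", ]
  expect_equal(c(sev$precision, sev$recall, sev$f1), c(0, 0, 0))
  # perfect predictions over all seven positive types
  full <- rep(RELATION_TYPES, each = 2)
  ev2 <- score(full, full)
  expect_equal(ev2$macro_f1, 100)
  expect_true(all(ev2$per_class$f1[ev2$per_class$tp > 0] == 100))
  expect_error(score(gold, pred[-1]), class = "relex_eval_error")
})

test_that("macro averages exclude None and match a confusion-matrix oracle", {
  set.seed(33)
  labels <- ALL_LABELS
  for (rep in 1:1000) {
    n <- sample(5:40, 1)
    gold <- sample(labels, n, replace = TRUE)
    pred <- sample(labels, n, replace = TRUE)
    ev <- score(gold, pred)
    # oracle: explicit confusion matrix over the positive types
    ps <- rs <- fs <- numeric(length(RELATION_TYPES))
    for (i in seq_along(RELATION_TYPES)) {
      l <- RELATION_TYPES[i]
      tp <- sum(gold == l & pred == l)
      fp <- sum(pred == l & gold != l)
      fn <- sum(gold == l & pred != l)
      ps[i] <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
      rs[i] <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
      fs[i] <- if (ps[i] + rs[i] == 0) 0 else 2 * ps[i] * rs[i] / (ps[i] + rs[i])
    }
    expect_equal(ev$macro_precision, mean(ps))
    expect_equal(ev$macro_recall, mean(rs))
    expect_equal(ev$macro_f1, mean(fs))
    # sum of positive TP equals count of correct positive predictions
    pc <- ev$per_class
    expect_equal(sum(pc$tp[pc$label %in% RELATION_TYPES]),
                 sum(gold == pred & gold %in% RELATION_TYPES))
  }
})

test_that("macro recomputation from printed per-class cells matches", {
  expect_equal(macro_from_cells(c(20, 7, 2, 1, 1, 1, 0)), 4.57)
  expect_equal(macro_from_cells(c(80, 78, 76, 69, 32, 46, 93)), 67.71)
})

test_that("distance-stratified scoring partitions correctly and flags empty bins", {
  gold <- c("Dosage", "Dosage", "None", "Route")
  pred <- c("Dosage", "None", "None", "Route")
  d <- c(1, 2, 15, 3)
  out <- distance_stratified_f1(gold, pred, d, edges = c(5, 10))
  expect_equal(nrow(out), 3)
  expect_equal(out$n, c(3L, 0L, 1L))
  expect_true(out$empty[2])
  expect_true(is.na(out$macro_f1[2]))
  # empty bin with no gold positives is flagged, not scored zero
  expect_true(out$empty[3]) # only a None example
  # single bin containing everything reproduces the global score over the
  # types with gold support
  all_in <- distance_stratified_f1(gold, pred, rep(0, 4), edges = 100)
  expect_equal(all_in$macro_f1[1],
               score(gold, pred, intersect(RELATION_TYPES, gold))$macro_f1)
  # perfect predictions: every non-empty bin at 100
  perf <- distance_stratified_f1(gold, gold, d, edges = c(5, 10))
  expect_true(all(perf$macro_f1[!perf$empty] == 100))
  expect_error(distance_stratified_f1(gold, pred, d, edges = c(10, 5)),
               class = "relex_eval_error")
})

test_that("stratified subsampling preserves label proportions and sources", {
  corpus <- fixture_corpus(n_docs = 30, relations_per_doc = 10, seed = 41)
  data <- fixture_experiment(corpus)
  sub <- stratified_subsample(data$train, 0.2, seed = 3)
  pos_full <- table(data$train$label[data$train$provenance == "gold"])
  pos_sub <- table(factor(sub$label[sub$provenance == "gold"],
                          levels = names(pos_full)))
  for (l in names(pos_full)) {
    expect_lte(abs(pos_sub[[l]] - round(0.2 * pos_full[[l]])), 1)
  }
  # negatives in the subsample derive from sampled relations
  sub_rel <- paste(sub$doc_id[sub$provenance == "gold"],
                   sub$source_rel[sub$provenance == "gold"])
  neg_rel <- paste(sub$doc_id[sub$provenance == "corrupted"],
                   sub$source_rel[sub$provenance == "corrupted"])
  expect_true(all(neg_rel %in% sub_rel))
  # fraction 1 returns the dataset unchanged
  expect_identical(stratified_subsample(data$train, 1, seed = 3), data$train)
  expect_error(stratified_subsample(data$train, 0, seed = 1),
               class = "relex_config_error")
})

test_that("the learning curve reproduces the full-data run at fraction 1", {
  corpus <- fixture_corpus(n_docs = 20, relations_per_doc = 8, seed = 42)
  data <- fixture_experiment(corpus)
  trainer <- function(train_subset, seed) {
    model <- fit_distance_bins(train_subset, data$docs)
    score(data$test$label,
          predict_rule_distance(model, dataset_distances(data$test, data$docs))
    )$macro_f1
  }
  curve <- learning_curve(data$train, fractions = c(0.5, 1), seeds = 7,
                          train_eval = trainer)
  expect_equal(nrow(curve), 2)
  full <- trainer(data$train, 7)
  expect_equal(curve$macro_f1[curve$fraction == 1], full)
})

test_that("sweeps run one evaluation per grid point with fixed dev/test sets", {
  corpus <- fixture_corpus(n_docs = 16, relations_per_doc = 6, seed = 43)
  seen_dev <- list()
  runner <- function(keep_rate, window_size) {
    data <- prepare_experiment(corpus, 2, keep_rate, seed = 5)
    seen_dev[[length(seen_dev) + 1]] <<- data$dev
    model <- fit_distance_bins(data$train, data$docs)
    f1 <- function(ds) score(ds$label,
                             predict_rule_distance(model,
                                                   dataset_distances(ds, data$docs)))$macro_f1
    c(train = f1(data$train), dev = f1(data$dev), test = f1(data$test))
  }
  res <- sweep_grid(keep_rates = c(0.1, 0.8), window_sizes = 10, runner)
  expect_equal(nrow(res), 2)
  expect_true(all(c("train_f1", "dev_f1", "test_f1") %in% names(res)))
  # dev candidate sets identical across keep rates
  expect_identical(seen_dev[[1]], seen_dev[[2]])
  # 1x1 grid: single row
  expect_equal(nrow(sweep_grid(0.5, 10, runner)), 1)
})
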