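#' Model choices of the framework
#'
#' @export
MODEL_CHOICES <- c("rule", "svm", "lstm", "bilstm", "lstm-att", "bilstm-att",
                   "bilstm-att-feat")

#' Assemble the candidate datasets of an experiment
#'
#' Runs the candidate-generation protocol over a split corpus: gold positives
#' plus corruption-generated negatives per split, with Bernoulli
#' down-sampling of the training negatives only. Development and test
#' candidate sets do not depend on the keep rate.
#'
#' @param corpus A `relex_corpus`.
#' @param corruptions_per_side Replacements per mention of each gold
#'   relation.
#' @param keep_rate Keep rate for training-negative down-sampling.
#' @param seed Integer seed.
#' @return List with `docs` (index over all splits) and `train`, `dev`,
#'   `test` datasets.
#' @export
prepare_experiment <- function(corpus, corruptions_per_side = 2,
                               keep_rate = 0.5, seed = 1) {
  seeds <- derive_seeds(seed, 7)
  docs <- doc_index(c(corpus$train, corpus$dev, corpus$test))
  neg_train <- generate_negatives(corpus$train, corruptions_per_side, seeds[1])
  neg_dev <- generate_negatives(corpus$dev, corruptions_per_side, seeds[2])
  neg_test <- generate_negatives(corpus$test, corruptions_per_side, seeds[3])
  list(
    docs = docs,
    train = build_dataset(corpus$train, downsample(neg_train, keep_rate, seeds[4]),
                          seed = seeds[5]),
    dev = build_dataset(corpus$dev, neg_dev, seed = seeds[6]),
    test = build_dataset(corpus$test, neg_test, seed = seeds[7])
  )
}

#' Train any of the framework's systems
#'
#' Dispatches to the rule-induction baseline, the SVM pipeline, or one of
#' the neural variants under a common interface.
#'
#' @param model One of [MODEL_CHOICES].
#' @param data An experiment from [prepare_experiment()].
#' @param resources Feature resources for the SVM (fitted on the training
#'   documents when `NULL`).
#' @param svm_grid Regularization grid for the SVM.
#' @param neural_opts Named list of overrides passed to [neural_config()].
#' @param embeddings Optional pretrained embeddings for the neural models.
#' @param seed Integer seed.
#' @return An object of class `relex_system`.
#' @export
train_system <- function(model, data, resources = NULL,
                         svm_grid = c(0.01, 0.1, 1, 10, 100),
                         neural_opts = list(), embeddings = NULL, seed = 1) {
  model <- match.arg(model, MODEL_CHOICES)
  fit <- switch(model,
    rule = fit_distance_bins(data$train, data$docs),
    svm = {
      if (is.null(resources)) {
        train_doc_ids <- unique(data$train$doc_id)
        resources <- fit_feature_resources(data$docs[train_doc_ids])
      }
      train_svm(data$train, data$dev, data$docs, resources,
                grid = svm_grid, seed = seed)
    },
    {
      nc <- do.call(neural_config_for,
                    c(list(model = model, seed = seed), neural_opts))
      train_neural(nc, data$train, data$dev, data$docs,
                   embeddings = embeddings)
    }
  )
  structure(list(model = model, fit = fit), class = "relex_system")
}

#' @rdname train_system
#' @param system A trained `relex_system`.
#' @param dataset Examples to classify.
#' @param docs Named document list.
#' @export
predict_system <- function(system, dataset, docs) {
  switch(system$model,
    rule = predict_rule_distance(system$fit, dataset_distances(dataset, docs)),
    svm = predict_svm(system$fit, dataset, docs),
    predict_neural(system$fit, dataset, docs)
  )
}

#' Score a trained system on the train/dev/test datasets
#'
#' @param system A `relex_system`.
#' @param data An experiment from [prepare_experiment()].
#' @return List of `relex_eval` reports, one per split.
#' @export
evaluate_system <- function(system, data) {
  lapply(data[c("train", "dev", "test")], function(ds) {
    score(ds$label, predict_system(system, ds, data$docs))
  })
}

#' Run a keep-rate / window-size sweep for one model
#'
#' Reproduces the down-sampling and context-window protocols: one
#' train/evaluate cycle per grid point with a fixed seed, keeping the
#' development and test candidate sets constant across keep rates.
#'
#' @param corpus A `relex_corpus`.
#' @param model One of [MODEL_CHOICES].
#' @param keep_rates Keep rates to sweep (default `c(0.1, 0.3, 0.5, 0.8)`).
#' @param window_sizes Window sizes to sweep (default 30; only meaningful
#'   for neural models).
#' @param corruptions_per_side Candidate-generation multiplicity.
#' @param neural_opts Overrides for [neural_config()].
#' @param seed Integer seed.
#' @return Data frame from [sweep_grid()].
#' @export
run_sweep <- function(corpus, model, keep_rates = c(0.1, 0.3, 0.5, 0.8),
                      window_sizes = 30, corruptions_per_side = 2,
                      neural_opts = list(), seed = 1) {
  sweep_grid(keep_rates, window_sizes, function(keep_rate, window_size) {
    data <- prepare_experiment(corpus, corruptions_per_side, keep_rate, seed)
    opts <- utils::modifyList(neural_opts, list(window = window_size))
    sys <- train_system(model, data,
                        neural_opts = if (model %in% c("rule", "svm")) list() else opts,
                        seed = seed)
    evs <- evaluate_system(sys, data)
    c(train = evs$train$macro_f1, dev = evs$dev$macro_f1,
      test = evs$test$macro_f1)
  })
}
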