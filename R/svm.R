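#' Train the linear SVM relation classifier with grid search
#'
#' Fits a one-vs-rest ensemble of linear-kernel SVMs (via \pkg{e1071}) over
#' the sparse feature space of [extract_features()]. For each regularization
#' value in `grid`, the ensemble is fitted on the training set and scored by
#' macro-F1 on the development set; the best value is then refitted on the
#' union of training and development data. No sentence-specific features are
#' used, so intra- and intersentential relations are classified jointly by
#' the single model.
#'
#' @param train_dataset,dev_dataset Labeled `relex_dataset`s.
#' @param docs Named document list covering both datasets.
#' @param resources A fitted `relex_resources`.
#' @param grid Regularization (cost) values to search (default
#'   `c(0.01, 0.1, 1, 10, 100)`).
#' @param seed Integer seed (e1071's solver is deterministic; the seed fixes
#'   any residual tie-breaking).
#' @return An object of class `relex_svm` with per-class weight vectors `W`
#'   (features x classes), biases `b`, the feature `vocab`, the selected
#'   `cost` and the grid-search `trace`.
#' @export
train_svm <- function(train_dataset, dev_dataset, docs, resources,
                      grid = c(0.01, 0.1, 1, 10, 100), seed = 1) {
  if (length(grid) == 0) stop_relex("empty grid", "relex_config_error")
  if (length(unique(train_dataset$label)) < 2) {
    stop_relex("training data contains a single class", "relex_fit_error")
  }
  fm <- build_feature_matrix(train_dataset, docs, resources)
  x_train <- fm$matrix
  x_dev <- build_feature_matrix(dev_dataset, docs, resources, fm$vocab)$matrix
  trace <- data.frame(cost = grid, dev_macro_f1 = NA_real_)
  best <- NULL
  for (gi in seq_along(grid)) {
    fit <- with_seed(seed, fit_ovr(x_train, train_dataset$label, grid[gi]))
    pred <- ovr_predict(fit, x_dev)
    trace$dev_macro_f1[gi] <- score(dev_dataset$label, pred)$macro_f1
    if (is.null(best) || trace$dev_macro_f1[gi] > best$f1) {
      best <- list(cost = grid[gi], f1 = trace$dev_macro_f1[gi])
    }
  }
  x_all <- rbind(x_train, x_dev)
  y_all <- c(train_dataset$label, dev_dataset$label)
  final <- with_seed(seed, fit_ovr(x_all, y_all, best$cost))
  structure(
    list(W = final$W, b = final$b, classes = final$classes,
         vocab = fm$vocab, cost = best$cost, trace = trace,
         resources = resources),
    class = "relex_svm"
  )
}

# One-vs-rest linear SVM ensemble: one binary machine per class, scored by
# its signed decision value.
fit_ovr <- function(x, y, cost) {
  classes <- sort(unique(y))
  p <- ncol(x)
  W <- matrix(0, nrow = p, ncol = length(classes),
              dimnames = list(colnames(x), classes))
  b <- stats::setNames(numeric(length(classes)), classes)
  for (ci in seq_along(classes)) {
    ybin <- factor(ifelse(y == classes[ci], "pos", "neg"),
                   levels = c("pos", "neg"))
    m <- e1071::svm(x, ybin, kernel = "linear", cost = cost, scale = FALSE)
    sv <- m$SV
    if (inherits(sv, "matrix.csr")) {
      # e1071 stores support vectors in SparseM row-compressed form
      rows <- rep(seq_len(sv@dimension[1]), diff(sv@ia))
      sv <- Matrix::sparseMatrix(i = rows, j = sv@ja, x = sv@ra,
                                 dims = sv@dimension)
    }
    w <- as.numeric(Matrix::crossprod(sv, as.numeric(m$coefs)))
    rho <- m$rho
    # e1071 orients the decision value toward its internal first label
    if (levels(ybin)[m$labels[1]] != "pos") {
      w <- -w
      rho <- -rho
    }
    W[, ci] <- w
    b[ci] <- -rho
  }
  list(W = W, b = b, classes = classes)
}

ovr_predict <- function(fit, x) {
  scores <- as.matrix(x %*% fit$W)
  scores <- sweep(scores, 2, fit$b, `+`)
  # deterministic argmax; ties break toward the lexicographically first label
  ord <- order(fit$classes)
  scores <- scores[, ord, drop = FALSE]
  fit$classes[ord][max.col(scores, ties.method = "first")]
}

#' Predict relation labels with a fitted SVM model
#'
#' @param model A `relex_svm`.
#' @param dataset A `relex_dataset` of examples to classify.
#' @param docs Named document list covering the dataset.
#' @return Character vector of predicted labels.
#' @export
predict_svm <- function(model, dataset, docs) {
  x <- build_feature_matrix(dataset, docs, model$resources, model$vocab)$matrix
  ovr_predict(model, x)
}

#' Persist or load a fitted SVM model directory
#'
#' Writes plain-text artifacts: the weight matrix in MatrixMarket format,
#' biases, classes, the feature vocabulary, and the selected hyperparameters.
#' Feature resources are not serialized; supply them again at load time.
#'
#' @param model A `relex_svm`.
#' @param dir Target directory.
#' @param resources The `relex_resources` to attach on load.
#' @export
write_svm_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(model$W, sparse = TRUE),
                  file.path(dir, "weights.mtx"))
  writeLines(model$classes, file.path(dir, "classes.txt"))
  writeLines(model$vocab, file.path(dir, "vocab.txt"))
  utils::write.table(data.frame(class = model$classes, bias = model$b),
                     file.path(dir, "bias.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(cost = model$cost), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(dir, resources) {
  W <- as.matrix(Matrix::readMM(file.path(dir, "weights.mtx")))
  classes <- readLines(file.path(dir, "classes.txt"))
  vocab <- readLines(file.path(dir, "vocab.txt"))
  dimnames(W) <- list(vocab, classes)
  bias <- utils::read.delim(file.path(dir, "bias.tsv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  structure(
    list(W = W, b = stats::setNames(bias$bias, bias$class), classes = classes,
         vocab = vocab, cost = cfg$cost, trace = NULL, resources = resources),
    class = "relex_svm"
  )
}
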