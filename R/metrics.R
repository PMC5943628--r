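#' Score predictions with per-class and macro-averaged metrics
#'
#' Computes per-label true positives, false positives and false negatives,
#' and from them precision `p = TP/(TP+FP)`, recall `r = TP/(TP+FN)` and
#' `F1 = 2pr/(p+r)`, with a 0/0 ratio defined as 0. The macro average is the
#' unweighted mean over the positive relation types of the schema; the
#' `None` class is reported per class but never enters the macro. Values are
#' on the percentage scale.
#'
#' @param gold Character vector of gold labels.
#' @param pred Character vector of predicted labels, same length.
#' @param positive_labels Labels entering the macro average (default the
#'   seven positive relation types).
#' @return An object of class `relex_eval` with fields `per_class` (data
#'   frame), `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
score <- function(gold, pred, positive_labels = RELATION_TYPES) {
  if (length(gold) != length(pred)) {
    stop_relex("gold and predicted label sequences differ in length",
               "relex_eval_error")
  }
  labels <- unique(c(positive_labels, NONE_LABEL, gold, pred))
  per <- data.frame(label = labels, tp = 0L, fp = 0L, fn = 0L,
                    precision = 0, recall = 0, f1 = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    l <- labels[i]
    per$tp[i] <- sum(gold == l & pred == l)
    per$fp[i] <- sum(pred == l & gold != l)
    per$fn[i] <- sum(gold == l & pred != l)
  }
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  per$precision <- 100 * safe_div(per$tp, per$tp + per$fp)
  per$recall <- 100 * safe_div(per$tp, per$tp + per$fn)
  per$f1 <- safe_div(2 * per$precision * per$recall,
                     per$precision + per$recall)
  pos <- per[per$label %in% positive_labels, , drop = FALSE]
  structure(
    list(per_class = per,
         macro_precision = mean(pos$precision),
         macro_recall = mean(pos$recall),
         macro_f1 = mean(pos$f1)),
    class = "relex_eval"
  )
}

#' @export
print.relex_eval <- function(x, ...) {
  per <- x$per_class
  per$precision <- round(per$precision, 2)
  per$recall <- round(per$recall, 2)
  per$f1 <- round(per$f1, 2)
  print(per[, c("label", "tp", "fp", "fn", "precision", "recall", "f1")],
        row.names = FALSE)
  cat(sprintf("Overall (macro over positives): P %.2f  R %.2f  F1 %.2f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Recompute a macro average from printed per-class cells
#'
#' Utility for checking published result tables: the unweighted mean of a
#' per-class metric column, rounded to the two decimals such tables print.
#'
#' @param values Numeric vector of per-class metric values (percent).
#' @return The macro average rounded to 2 decimals.
#' @export
macro_from_cells <- function(values) {
  round(mean(values), 2)
}

#' Macro-F1 stratified by token distance
#'
#' Partitions examples into distance bins `[0, e1], (e1, e2], ...` given
#' sorted bin edges and scores each bin separately. Bins containing no gold
#' positive example are flagged empty (`NA` macro-F1) rather than scored 0.
#'
#' @param gold,pred Aligned label vectors.
#' @param distances Token distance per example.
#' @param edges Increasing numeric bin edges; the last bin is open-ended.
#' @param positive_labels Labels eligible for the macro average; within each
#'   bin the average runs over the eligible labels with gold support there.
#' @return Data frame with `bin`, `n`, `n_gold_positive`, `macro_f1`,
#'   `empty`.
#' @export
distance_stratified_f1 <- function(gold, pred, distances, edges,
                                   positive_labels = RELATION_TYPES) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop_relex("bin edges must be strictly increasing", "relex_eval_error")
  }
  if (length(gold) != length(pred) || length(gold) != length(distances)) {
    stop_relex("gold, pred and distances must be aligned", "relex_eval_error")
  }
  breaks <- c(-0.5, edges, Inf)
  bin <- cut(distances, breaks)
  out <- data.frame(bin = levels(bin), n = 0L, n_gold_positive = 0L,
                    macro_f1 = NA_real_, empty = TRUE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(levels(bin))) {
    sel <- bin == levels(bin)[i]
    out$n[i] <- sum(sel)
    out$n_gold_positive[i] <- sum(gold[sel] %in% positive_labels)
    if (out$n_gold_positive[i] > 0) {
      out$empty[i] <- FALSE
      present <- intersect(positive_labels, gold[sel])
      out$macro_f1[i] <- score(gold[sel], pred[sel], present)$macro_f1
    }
  }
  out
}

#' Stratified subsample of a training dataset
#'
#' Samples a fraction of the gold positives of each relation type (preserving
#' label proportions to within one example per class) and keeps the negatives
#' generated from the sampled relations, so a subsample is a coherent smaller
#' version of the same candidate-generation protocol.
#'
#' @param dataset A training `relex_dataset`.
#' @param fraction Fraction in `(0, 1]`; 1 returns the dataset unchanged.
#' @param seed Integer seed.
#' @return A `relex_dataset` subset.
#' @export
stratified_subsample <- function(dataset, fraction, seed = 1) {
  if (fraction <= 0 || fraction > 1) {
    stop_relex("fraction must lie in (0, 1]", "relex_config_error")
  }
  if (fraction == 1) return(dataset)
  with_seed(seed, {
    pos <- dataset[dataset$provenance == "gold", , drop = FALSE]
    keep_keys <- character(0)
    for (l in unique(pos$label)) {
      rows <- which(pos$label == l)
      k <- round(fraction * length(rows))
      if (k == 0) {
        warning(sprintf("fraction %.2f yields no examples for class %s; class dropped",
                        fraction, l))
        next
      }
      sel <- sample(rows, k)
      keep_keys <- c(keep_keys, paste(pos$doc_id[sel], pos$source_rel[sel]))
    }
    src_key <- paste(dataset$doc_id, dataset$source_rel)
    out <- dataset[src_key %in% keep_keys, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("relex_dataset", "data.frame")
    out
  })
}

#' Learning curve over training-set fractions
#'
#' For each fraction and seed, draws a stratified subsample of the training
#' data with [stratified_subsample()] and calls `train_eval(subsample, seed)`,
#' which must train a system and return its test macro-F1.
#'
#' @param train_dataset The full training `relex_dataset`.
#' @param fractions Fractions in `(0, 1]`.
#' @param seeds Integer seeds (one run per fraction x seed).
#' @param train_eval Function `(dataset, seed) -> numeric macro-F1`.
#' @return Data frame with `fraction`, `seed`, `macro_f1`.
#' @export
learning_curve <- function(train_dataset, fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                           seeds = 1, train_eval = NULL) {
  stopifnot(is.function(train_eval))
  grid <- expand.grid(fraction = fractions, seed = seeds)
  grid$macro_f1 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sub <- stratified_subsample(train_dataset, grid$fraction[i], grid$seed[i])
    grid$macro_f1[i] <- train_eval(sub, grid$seed[i])
  }
  grid
}

#' Keep-rate and window-size sweep
#'
#' Runs one train/evaluate cycle per grid point with a fixed seed and
#' collects train/dev/test macro-F1. The runner receives a keep rate and a
#' window size and must return a named numeric vector with elements `train`,
#' `dev`, `test`. Development and test candidate sets must not vary with the
#' keep rate; only training negatives are down-sampled.
#'
#' @param keep_rates Numeric vector of negative down-sampling keep rates.
#' @param window_sizes Integer vector of context window sizes.
#' @param runner Function `(keep_rate, window_size) -> c(train=, dev=,
#'   test=)`.
#' @return Data frame with one row per grid point.
#' @export
sweep_grid <- function(keep_rates, window_sizes, runner) {
  grid <- expand.grid(keep_rate = keep_rates, window_size = window_sizes)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    runner(grid$keep_rate[i], grid$window_size[i])
  })
  grid$train_f1 <- vapply(res, function(r) unname(r[["train"]]), numeric(1))
  grid$dev_f1 <- vapply(res, function(r) unname(r[["dev"]]), numeric(1))
  grid$test_f1 <- vapply(res, function(r) unname(r[["test"]]), numeric(1))
  grid
}
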