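#' Fit the distance-bin rule induction baseline
#'
#' Computes the unweighted arithmetic mean token distance of the gold
#' positive examples of each relation type, sorts the types by mean
#' ascending, and defines consecutive distance bins: the first bin is
#' `[0, m1]` and each subsequent bin is `(m_(i-1), m_i]`. Negative examples
#' never enter fitting. A tie between two means is broken toward the type
#' with more training instances; the losing type's bin is empty and the type
#' is dropped with a warning, as is any type absent from the training data.
#'
#' @param dataset A `relex_dataset` of training examples (only gold
#'   positives are used).
#' @param docs A named document list from [doc_index()] covering the dataset.
#' @return An object of class `relex_rule_model` with fields `bins` (data
#'   frame of `label`, `upper_bound`) and `means` (named numeric of fitted
#'   per-type mean distances).
#' @export
fit_distance_bins <- function(dataset, docs) {
  pos <- dataset[dataset$label %in% RELATION_TYPES &
                   dataset$provenance == "gold", , drop = FALSE]
  if (nrow(pos) == 0) {
    stop_relex("no gold positive examples to fit distance bins",
               "relex_fit_error")
  }
  d <- dataset_distances(pos, docs)
  means <- tapply(d, factor(pos$label, levels = RELATION_TYPES), mean)
  counts <- table(factor(pos$label, levels = RELATION_TYPES))
  missing <- names(means)[is.na(means)]
  if (length(missing) > 0) {
    warning(sprintf("no training examples for type(s): %s; omitted from bins",
                    paste(missing, collapse = ", ")))
  }
  present <- names(means)[!is.na(means)]
  ord <- present[order(means[present], -as.numeric(counts[present]))]
  m_sorted <- as.numeric(means[ord])
  # a mean equal to its predecessor would create an empty interval
  dup <- c(FALSE, diff(m_sorted) == 0)
  if (any(dup)) {
    warning(sprintf("tied mean distances; dropping type(s) with fewer instances: %s",
                    paste(ord[dup], collapse = ", ")))
  }
  bins <- data.frame(label = ord[!dup], upper_bound = m_sorted[!dup],
                     stringsAsFactors = FALSE)
  structure(list(bins = bins, means = means[!is.na(means)]),
            class = "relex_rule_model")
}

#' Predict relation labels from token distance
#'
#' A distance falling in bin i receives that bin's label; distance 0 falls in
#' the first bin; a distance beyond the last bound is labeled `None`.
#'
#' @param model A fitted `relex_rule_model`.
#' @param distance Numeric vector of token distances.
#' @return Character vector of labels.
#' @export
predict_rule_distance <- function(model, distance) {
  uppers <- model$bins$upper_bound
  labels <- model$bins$label
  vapply(distance, function(d) {
    i <- which(d <= uppers)[1]
    if (is.na(i)) NONE_LABEL else labels[i]
  }, character(1))
}

#' @rdname predict_rule_distance
#' @param doc A `relex_document`.
#' @param left_id,right_id The mention pair to classify.
#' @export
predict_rule <- function(model, doc, left_id, right_id) {
  predict_rule_distance(model, token_distance(doc, left_id, right_id))
}

#' @export
print.relex_rule_model <- function(x, ...) {
  cat("<relex_rule_model>\n")
  lower <- c(0, x$bins$upper_bound[-nrow(x$bins)])
  for (i in seq_len(nrow(x$bins))) {
    cat(sprintf("  %s: (%g, %g]%s\n", x$bins$label[i], lower[i],
                x$bins$upper_bound[i], if (i == 1) " (0 included)" else ""))
  }
  invisible(x)
}

#' Serialize or load a rule model
#'
#' @param model A `relex_rule_model`.
#' @param path JSON file path.
#' @export
write_rule_model <- function(model, path) {
  jsonlite::write_json(
    list(bins = model$bins, means = as.list(model$means)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_rule_model
#' @export
read_rule_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(bins = x$bins, means = unlist(x$means)),
            class = "relex_rule_model")
}
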