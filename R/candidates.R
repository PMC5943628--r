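#' Generate None-relation candidates by corrupting gold relations
#'
#' For each gold relation, each of its two mentions is replaced in turn by up
#' to `corruptions_per_side` other mentions from the same document (sampled
#' uniformly without replacement, excluding OtherSS mentions and mentions
#' overlapping the kept one). A corrupted pair is rejected if it matches any
#' gold positive pair of its document or a previously emitted negative.
#' Documents with fewer than three usable mentions contribute no negatives
#' (reported via a message, not an error).
#'
#' @param docs A list of `relex_document` objects (one corpus split).
#' @param corruptions_per_side Maximum replacements per mention of each gold
#'   relation. The default of 45 yields roughly 90 negatives per positive on
#'   a dense corpus, matching the negative-to-positive ratio of the protocol
#'   this package implements at full scale.
#' @param seed Integer seed.
#' @return A data frame of class `relex_dataset` rows: `doc_id`, `left_id`,
#'   `right_id`, `label` (always `"None"`), `provenance` (`"corrupted"`),
#'   `source_rel` (id of the corrupted gold relation).
#' @export
generate_negatives <- function(docs, corruptions_per_side = 45, seed = 1) {
  if (corruptions_per_side < 0) {
    stop_relex("corruptions_per_side must be >= 0", "relex_config_error")
  }
  with_seed(seed, {
    out <- vector("list", length(docs))
    skipped <- 0L
    for (k in seq_along(docs)) {
      doc <- docs[[k]]
      mn <- doc$mentions
      rl <- doc$relations
      if (nrow(rl) == 0) next
      usable <- mn$id[mn$etype != "OtherSS"]
      if (length(usable) < 3) {
        skipped <- skipped + 1L
        next
      }
      gold_keys <- paste(rl$left_id, rl$right_id)
      seen <- new.env(parent = emptyenv())
      for (g in gold_keys) assign(g, TRUE, envir = seen)
      acc_left <- character(0); acc_right <- character(0); acc_src <- character(0)
      for (i in seq_len(nrow(rl))) {
        for (side in c("left", "right")) {
          keep_id <- if (side == "left") rl$right_id[i] else rl$left_id[i]
          orig_id <- if (side == "left") rl$left_id[i] else rl$right_id[i]
          keep <- mention_row(doc, keep_id)
          cands <- setdiff(usable, c(keep_id, orig_id))
          if (length(cands) == 0 || corruptions_per_side == 0) next
          cands <- sample(cands, length(cands))
          taken <- 0L
          for (cand in cands) {
            if (taken >= corruptions_per_side) break
            cm <- mention_row(doc, cand)
            if (cm$first_token <= keep$last_token &&
                keep$first_token <= cm$last_token) next # overlap: no distance
            lr <- order_pair(doc, cand, keep_id)
            key <- paste(lr[1], lr[2])
            if (!is.null(seen[[key]])) next
            assign(key, TRUE, envir = seen)
            acc_left <- c(acc_left, lr[1])
            acc_right <- c(acc_right, lr[2])
            acc_src <- c(acc_src, rl$id[i])
            taken <- taken + 1L
          }
        }
      }
      if (length(acc_left) > 0) {
        out[[k]] <- data.frame(
          doc_id = doc$doc_id, left_id = acc_left, right_id = acc_right,
          label = NONE_LABEL, provenance = "corrupted", source_rel = acc_src,
          stringsAsFactors = FALSE
        )
      }
    }
    if (skipped > 0) {
      message(sprintf("%d document(s) had < 3 usable mentions; no negatives generated for them",
                      skipped))
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(res)) {
      res <- data.frame(doc_id = character(), left_id = character(),
                        right_id = character(), label = character(),
                        provenance = character(), source_rel = character(),
                        stringsAsFactors = FALSE)
    }
    class(res) <- c("relex_dataset", "data.frame")
    res
  })
}

#' Down-sample negative examples
#'
#' Retains each negative independently with probability `keep_rate`
#' (Bernoulli down-sampling). Intended for the training split only; the
#' development and test candidate sets are kept unchanged across keep rates.
#'
#' @param negatives A data frame of negative examples.
#' @param keep_rate Retention probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The retained subset, same columns.
#' @export
downsample <- function(negatives, keep_rate, seed = 1) {
  if (!is.numeric(keep_rate) || keep_rate < 0 || keep_rate > 1) {
    stop_relex("keep_rate must lie in [0, 1]", "relex_config_error")
  }
  if (keep_rate == 1) return(negatives)
  with_seed(seed, {
    keep <- stats::runif(nrow(negatives)) < keep_rate
    negatives[keep, , drop = FALSE]
  })
}

#' Extract gold positive examples from documents
#'
#' @param docs A list of `relex_document` objects.
#' @return A `relex_dataset` data frame with `provenance = "gold"`.
#' @export
gold_examples <- function(docs) {
  out <- lapply(docs, function(doc) {
    rl <- doc$relations
    if (nrow(rl) == 0) return(NULL)
    data.frame(doc_id = doc$doc_id, left_id = rl$left_id,
               right_id = rl$right_id, label = rl$label,
               provenance = "gold", source_rel = rl$id,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(doc_id = character(), left_id = character(),
                      right_id = character(), label = character(),
                      provenance = character(), source_rel = character(),
                      stringsAsFactors = FALSE)
  }
  class(res) <- c("relex_dataset", "data.frame")
  res
}

#' Assemble a labeled dataset from gold positives and generated negatives
#'
#' Concatenates gold examples of the split with the supplied negatives,
#' removes duplicates (with a warning), and shuffles deterministically when a
#' seed is given.
#'
#' @param docs A list of `relex_document` objects (the split).
#' @param negatives Negative examples for the same split.
#' @param seed Optional integer seed for shuffling; `NULL` keeps input order.
#' @return A `relex_dataset` data frame.
#' @export
build_dataset <- function(docs, negatives = NULL, seed = NULL) {
  pos <- gold_examples(docs)
  ds <- if (is.null(negatives) || nrow(negatives) == 0) pos else {
    rbind(pos, negatives[, names(pos)])
  }
  key <- paste(ds$doc_id, ds$left_id, ds$right_id, ds$label)
  if (anyDuplicated(key)) {
    warning("duplicate examples removed from dataset")
    ds <- ds[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(seed)) {
    ds <- with_seed(seed, ds[sample.int(nrow(ds)), , drop = FALSE])
  }
  rownames(ds) <- NULL
  class(ds) <- c("relex_dataset", "data.frame")
  ds
}

#' Token distances for every example of a dataset
#'
#' @param dataset A `relex_dataset`.
#' @param docs A named document list from [doc_index()].
#' @return Integer vector of token distances, aligned with dataset rows.
#' @export
dataset_distances <- function(dataset, docs) {
  vapply(seq_len(nrow(dataset)), function(i) {
    token_distance(docs[[dataset$doc_id[i]]],
                   dataset$left_id[i], dataset$right_id[i])
  }, integer(1))
}

#' Read or write a dataset as delimited text
#'
#' @param dataset A `relex_dataset`.
#' @param path File path (TSV).
#' @export
write_dataset <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(ds) <- c("relex_dataset", "data.frame")
  ds
}
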