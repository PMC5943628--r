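#' Default type-specific lexicons for synthetic note generation
#'
#' Each entity type draws surface forms from its own small lexicon, so that
#' relation types are learnable from lexical plus distance signal. Surfaces
#' are alphanumeric (multi-token surfaces use spaces) so that documents
#' round-trip exactly through the tokenizer.
#'
#' @return Named list of character vectors, one per entity type, plus a
#'   `filler` vocabulary.
#' @export
default_lexicons <- function() {
  list(
    Medication = c("albuterol", "rituximab", "carfilzomib", "metformin",
                   "lisinopril", "warfarin", "ampicillin", "prednisone",
                   "romidepsin", "ponatinib", "ibrutinib", "dexamethasone",
                   "cytarabine", "vincristine", "omeprazole", "gabapentin"),
    Dosage = c("2 puffs", "10 mg", "20 mg", "40 mg", "100 mg", "250 mg",
               "500 mg", "1 tablet", "2 tablets", "5 ml", "1 unit"),
    Route = c("po", "iv", "oral", "topical", "subcutaneous", "intramuscular",
              "inhaled", "sublingual"),
    Frequency = c("daily", "bid", "tid", "qid", "weekly", "nightly", "qhs",
                  "q4h", "q6h", "prn", "monthly"),
    Duration = c("2 weeks", "5 days", "3 months", "10 days", "1 week",
                 "6 months", "1 year", "4 weeks"),
    Indication = c("lymphoma", "hypertension", "myeloma", "leukemia",
                   "diabetes", "pneumonia", "anemia", "asthma", "gerd",
                   "infection", "pain", "insomnia"),
    ADE = c("nausea", "rash", "neutropenia", "diarrhea", "vomiting",
            "mucositis", "thrombocytopenia", "neuropathy", "anaphylaxis",
            "hepatotoxicity", "dizziness", "constipation"),
    Severity = c("severe", "mild", "moderate", "worsening", "slight",
                 "profound", "marked"),
    OtherSS = c("fatigue", "cough", "fever", "chills", "headache", "edema",
                "malaise", "weakness", "sweats"),
    filler = c("patient", "the", "was", "noted", "to", "have", "continues",
               "on", "with", "his", "her", "and", "of", "for", "tolerated",
               "well", "clinic", "visit", "today", "stable", "reports",
               "denies", "exam", "followup", "plan", "will", "continue",
               "started", "since", "last", "review", "course", "status",
               "treatment", "cycle", "labs", "within", "normal", "limits")
  )
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the descriptive statistics of the clinical benchmark the
#' package targets: per-type relation frequencies proportional to the
#' benchmark training counts, short distances for drug-attribute relations,
#' long-tailed distances (mean 19 and 14) for Indication and Adverse
#' relations so that a share of relations crosses sentence boundaries, a
#' global mean token distance near 7, and a 602/95/94-proportioned
#' train/dev/test document split.
#'
#' @param n_docs Number of documents (default 791).
#' @param relations_per_doc Expected relations per document (Poisson mean,
#'   default 20).
#' @param rel_weights Named per-type relation rates (proportions are what
#'   matters).
#' @param dist_means Named per-type mean token distances.
#' @param dist_size Negative-binomial dispersion (`size`) of the distance
#'   distribution; small values give the right-skewed long tail.
#' @param sentence_break_prob Probability that a filler token is a
#'   sentence-final period; intersentential relations arise when a sampled
#'   distance spans one or more periods.
#' @param standalone_mention_prob Probability that a filler-run token is an
#'   unattached entity mention (enriches mention density and the corruption
#'   pool).
#' @param gap_mention_prob Probability that a between-pair gap token is an
#'   unattached OtherSS mention.
#' @param tokens_per_doc Approximate target document length, used for
#'   feasibility checking of distance means.
#' @param split Train/dev/test document proportions.
#' @param lexicons Entity lexicons, see [default_lexicons()].
#' @param seed Integer seed; the same seed yields a byte-identical corpus.
#' @return An object of class `relex_gen_config`.
#' @export
gen_config <- function(n_docs = 791,
                       relations_per_doc = 20,
                       rel_weights = c(Dosage = 2643, Route = 1908,
                                       Frequency = 2691, Duration = 493,
                                       Indication = 2301, Adverse = 717,
                                       Severity = 1505),
                       dist_means = c(Dosage = 1, Route = 2, Frequency = 5,
                                      Duration = 8, Indication = 19,
                                      Adverse = 14, Severity = 2),
                       dist_size = 2,
                       sentence_break_prob = 1 / 9,
                       standalone_mention_prob = 0.12,
                       gap_mention_prob = 0.08,
                       tokens_per_doc = 850,
                       split = c(train = 602, dev = 95, test = 94) / 791,
                       lexicons = default_lexicons(),
                       seed = 42) {
  if (any(rel_weights < 0) || all(rel_weights == 0)) {
    stop_relex("relation weights must be non-negative with a positive sum",
               "relex_config_error")
  }
  if (any(dist_means < 0)) {
    stop_relex("distance means must be non-negative", "relex_config_error")
  }
  if (any(dist_means[rel_weights > 0] > tokens_per_doc)) {
    stop_relex("infeasible config: distance mean exceeds document length",
               "relex_config_error")
  }
  unknown <- setdiff(names(rel_weights), RELATION_TYPES)
  if (length(unknown) > 0) {
    stop_relex(sprintf("unknown relation type in weights: %s", unknown[1]),
               "relex_config_error")
  }
  structure(
    list(n_docs = n_docs, relations_per_doc = relations_per_doc,
         rel_weights = rel_weights, dist_means = dist_means,
         dist_size = dist_size, sentence_break_prob = sentence_break_prob,
         standalone_mention_prob = standalone_mention_prob,
         gap_mention_prob = gap_mention_prob,
         tokens_per_doc = tokens_per_doc, split = split,
         lexicons = lexicons, seed = seed),
    class = "relex_gen_config"
  )
}

# Canonical document order of the two entity types of a relation: drug
# attributes typically follow drug names; severity modifiers precede the ADE.
canonical_first <- c(
  Dosage = "Medication", Route = "Medication", Frequency = "Medication",
  Duration = "Medication", Indication = "Medication", Adverse = "Medication",
  Severity = "Severity"
)

#' Generate a synthetic annotated corpus
#'
#' Builds documents token by token: each relation contributes its two typed
#' mentions separated by a sampled number of gap tokens, embedded in filler
#' text with probabilistic sentence breaks and unattached mentions. Per-type
#' token distances are drawn by stratified (quantile-grid) sampling from a
#' negative-binomial distribution, which reproduces the configured per-type
#' means closely while keeping the right-skewed, long-tailed shape; relations
#' whose gap spans a period are intersentential.
#'
#' @param config A [gen_config()].
#' @return An object of class `relex_corpus`: a list with `train`, `dev`,
#'   `test` document lists and the config as attribute `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "relex_gen_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n_docs <- config$n_docs
  empty <- structure(list(train = list(), dev = list(), test = list()),
                     config = config, class = "relex_corpus")
  if (n_docs == 0) return(empty)

  active <- names(config$rel_weights)[config$rel_weights > 0]
  # phase 1: relation counts and types per document
  n_rel <- stats::rpois(n_docs, config$relations_per_doc)
  types_by_doc <- lapply(n_rel, function(k) {
    if (k == 0) character(0)
    else sample(active, k, replace = TRUE,
                prob = config$rel_weights[active])
  })
  # phase 2: per-split, per-type distance pools via stratified quantile
  # sampling, so each split individually realizes the configured means
  n_train <- round(n_docs * config$split[[1]])
  n_dev <- round(n_docs * config$split[[2]])
  n_train <- min(n_train, n_docs)
  n_dev <- min(n_dev, n_docs - n_train)
  split_of <- rep(c("train", "dev", "test"),
                  c(n_train, n_dev, n_docs - n_train - n_dev))
  pools <- list()
  for (sp in unique(split_of)) {
    sp_types <- unlist(types_by_doc[split_of == sp])
    for (ty in active) {
      n_t <- sum(sp_types == ty)
      if (n_t == 0) next
      q <- stats::qnbinom((seq_len(n_t) - 0.5) / n_t,
                          mu = config$dist_means[[ty]],
                          size = config$dist_size)
      pools[[paste(sp, ty)]] <- sample(q)
    }
  }
  used <- stats::setNames(integer(length(pools)), names(pools))

  docs <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    docs[[d]] <- build_doc(sprintf("doc%04d", d), types_by_doc[[d]],
                           pools, used, config, split_of[d])
    used <- attr(docs[[d]], "used")
    attr(docs[[d]], "used") <- NULL
  }
  structure(
    list(train = docs[seq_len(n_train)],
         dev = docs[seq_len(n_dev) + n_train],
         test = docs[seq((n_train + n_dev + 1), length.out = n_docs - n_train - n_dev)]),
    config = config, class = "relex_corpus"
  )
}

# Assemble one document. `used` tracks per-type pool consumption.
build_doc <- function(doc_id, rel_types, pools, used, config, split) {
  lex <- config$lexicons
  surfaces <- character(0)
  m_id <- character(0); m_type <- character(0)
  m_first <- integer(0); m_last <- integer(0); m_text <- character(0)
  r_label <- character(0); r_left <- character(0); r_right <- character(0)
  n_mention <- 0L

  add_mention <- function(etype, surface_tokens) {
    n_mention <<- n_mention + 1L
    id <- paste0("T", n_mention)
    first <- length(surfaces)
    surfaces <<- c(surfaces, surface_tokens)
    m_id <<- c(m_id, id); m_type <<- c(m_type, etype)
    m_first <<- c(m_first, first)
    m_last <<- c(m_last, length(surfaces) - 1L)
    m_text <<- c(m_text, paste(surface_tokens, collapse = " "))
    id
  }
  sample_surface <- function(etype) {
    strsplit(sample(lex[[etype]], 1), " ", fixed = TRUE)[[1]]
  }
  emit_filler <- function(n, allow_standalone = TRUE) {
    for (i in seq_len(n)) {
      u <- stats::runif(1)
      if (u < config$sentence_break_prob) {
        surfaces <<- c(surfaces, ".")
      } else if (allow_standalone && u < config$sentence_break_prob +
                 config$standalone_mention_prob) {
        ty <- sample(ENTITY_TYPES, 1,
                     prob = c(rep(1, 8), 3)) # OtherSS over-represented
        add_mention(ty, sample_surface(ty)[1]) # standalone: single token
      } else {
        surfaces <<- c(surfaces, sample(lex$filler, 1))
      }
    }
  }
  emit_gap <- function(n) {
    for (i in seq_len(n)) {
      u <- stats::runif(1)
      if (u < config$sentence_break_prob) {
        surfaces <<- c(surfaces, ".")
      } else if (u < config$sentence_break_prob + config$gap_mention_prob) {
        add_mention("OtherSS", sample(lex$OtherSS, 1))
      } else {
        surfaces <<- c(surfaces, sample(lex$filler, 1))
      }
    }
  }

  for (ty in rel_types) {
    emit_filler(1L + stats::rgeom(1, 0.4))
    key <- paste(split, ty)
    used[[key]] <- used[[key]] + 1L
    d <- pools[[key]][used[[key]]]
    pair <- relation_schema(ty)
    first_type <- canonical_first[[ty]]
    second_type <- setdiff(pair, first_type)
    if (stats::runif(1) > 0.85) { # occasionally reverse document order
      tmp <- first_type; first_type <- second_type; second_type <- tmp
    }
    id1 <- add_mention(first_type, sample_surface(first_type))
    emit_gap(d)
    id2 <- add_mention(second_type, sample_surface(second_type))
    r_label <- c(r_label, ty)
    r_left <- c(r_left, id1)
    r_right <- c(r_right, id2)
  }
  emit_filler(2L + stats::rgeom(1, 0.4))
  surfaces <- c(surfaces, ".")

  # drop accidental duplicate gold pairs (same pair cannot relate twice)
  # (cannot occur by construction: every relation creates fresh mentions)

  sent <- c(0L, cumsum(surfaces == ".")[-length(surfaces)])
  nch <- nchar(surfaces)
  char_start <- cumsum(c(0L, nch[-length(nch)] + 1L))
  tokens <- data.frame(
    surface = surfaces, char_start = char_start,
    char_end = char_start + nch, sentence_index = as.integer(sent),
    token_index = seq_along(surfaces) - 1L, stringsAsFactors = FALSE
  )
  mentions <- data.frame(
    id = m_id, etype = m_type, first_token = m_first, last_token = m_last,
    text = m_text, stringsAsFactors = FALSE
  )
  relations <- if (length(r_label) > 0) {
    data.frame(id = paste0("R", seq_along(r_label)), label = r_label,
               left_id = r_left, right_id = r_right, stringsAsFactors = FALSE)
  } else NULL
  doc <- relex_document(doc_id, paste(surfaces, collapse = " "), tokens,
                        mentions, relations)
  attr(doc, "used") <- used
  doc
}

#' Descriptive statistics of an annotated corpus
#'
#' @param corpus A `relex_corpus` (split) or a plain list of documents.
#' @return An object of class `relex_corpus_stats` with per-type relation
#'   counts, the token-distance histogram, mean/max distance, and per-document
#'   mention and relation densities.
#' @export
corpus_stats <- function(corpus) {
  docs <- if (inherits(corpus, "relex_corpus") ||
              all(c("train", "dev", "test") %in% names(corpus))) {
    c(corpus$train, corpus$dev, corpus$test)
  } else corpus
  dists <- integer(0)
  labels <- character(0)
  n_mentions <- 0L
  for (doc in docs) {
    n_mentions <- n_mentions + nrow(doc$mentions)
    rl <- doc$relations
    for (i in seq_len(nrow(rl))) {
      dists <- c(dists, token_distance(doc, rl$left_id[i], rl$right_id[i]))
      labels <- c(labels, rl$label[i])
    }
  }
  per_type <- table(factor(labels, levels = RELATION_TYPES))
  structure(
    list(
      n_docs = length(docs),
      per_type_counts = per_type,
      n_relations = length(labels),
      distance_histogram = table(dists),
      mean_distance = if (length(dists)) mean(dists) else NA_real_,
      max_distance = if (length(dists)) max(dists) else NA_integer_,
      mentions_per_doc = if (length(docs)) n_mentions / length(docs) else NA_real_,
      relations_per_doc = if (length(docs)) length(labels) / length(docs) else NA_real_,
      distances = dists,
      labels = labels
    ),
    class = "relex_corpus_stats"
  )
}

#' @export
print.relex_corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus: %d docs, %d relations, mean distance %.2f, max %d>\n",
              x$n_docs, x$n_relations, x$mean_distance, x$max_distance))
  print(x$per_type_counts)
  invisible(x)
}

#' Serialize or load a generator configuration
#'
#' @param config A `relex_gen_config`.
#' @param path File path (YAML).
#' @return `read_gen_config()` returns a `relex_gen_config`.
#' @export
write_gen_config <- function(config, path) {
  x <- unclass(config)
  for (f in c("rel_weights", "dist_means", "split")) x[[f]] <- as.list(x[[f]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_gen_config
#' @export
read_gen_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(gen_config, lapply(x, function(v) {
    if (is.list(v) && !is.null(names(v)) && all(vapply(v, is.numeric, logical(1)))) {
      unlist(v)
    } else if (is.list(v) && all(vapply(v, is.character, logical(1)))) {
      v
    } else v
  }))
}
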