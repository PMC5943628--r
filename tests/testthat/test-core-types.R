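test_that("tokenizer splits words and punctuation with sentence segmentation", {
  tk <- tokenize("He has severe diarrhea.")
  expect_equal(tk$surface, c("He", "has", "severe", "diarrhea", "."))
  expect_true(all(tk$sentence_index == 0))

  tk2 <- tokenize("She receives Albuterol 2 puffs p.o. q4-6h")
  expect_true(all(c("Albuterol", "2", "puffs") %in% tk2$surface))

  tk3 <- tokenize("A. B.")
  expect_equal(tk3$sentence_index, c(0L, 0L, 1L, 1L))

  expect_error(tokenize("   "), class = "relex_empty_document_error")
})

test_that("tokenizer covers every non-whitespace character", {
  texts <- c("He has severe diarrhea.",
             "She receives Albuterol 2 puffs p.o. q4-6h",
             "dose: 20 mg/day (oral); review in 2 weeks!")
  for (txt in texts) {
    tk <- tokenize(txt)
    expect_equal(paste(tk$surface, collapse = ""),
                 gsub("[[:space:]]", "", txt))
    # offsets point back into the text
    expect_equal(substring(txt, tk$char_start + 1, tk$char_end), tk$surface)
  }
})

test_that("standoff reading aligns mentions and resolves relations", {
  txt <- "She receives Albuterol 2 puffs p.o. q4-6h"
  ann <- paste(
    "T1\tMedication 13 22\tAlbuterol",
    "T2\tDosage 23 30\t2 puffs",
    "R1\tDosage Arg1:T1 Arg2:T2",
    sep = "\n"
  )
  doc <- read_standoff(txt, ann)
  m <- doc$mentions
  expect_equal(m$text[m$id == "T1"], "Albuterol")
  expect_equal(m$first_token[m$id == "T1"], 2L)
  expect_equal(m$last_token[m$id == "T1"], 2L)
  expect_equal(doc$relations$label, "Dosage")

  # dangling relation argument
  expect_error(
    read_standoff(txt, "T1\tMedication 13 22\tAlbuterol\nR1\tDosage Arg1:T1 Arg2:T9"),
    class = "relex_dangling_argument_error"
  )
  # offsets outside the text
  expect_error(read_standoff(txt, "T1\tMedication 13 99\tx"),
               class = "relex_parse_error")
  # unknown entity type
  expect_error(read_standoff(txt, "T1\tGadget 13 22\tAlbuterol"),
               class = "relex_parse_error")
  # empty annotation content
  empty <- read_standoff(txt, "")
  expect_equal(nrow(empty$mentions), 0L)
  expect_equal(nrow(empty$relations), 0L)
})

test_that("standoff writing round-trips and rejects newlines in mentions", {
  doc <- fixture_doc()
  so <- write_standoff(doc)
  back <- read_standoff(so$text, so$ann, doc_id = doc$doc_id)
  expect_equal(back$mentions, doc$mentions)
  expect_equal(back$relations, doc$relations)
  expect_equal(back$tokens$surface, doc$tokens$surface)

  doc0 <- fixture_doc()
  doc0$relations <- doc0$relations[0, ]
  so0 <- write_standoff(doc0)
  expect_false(grepl("^R", so0$ann))

  bad <- fixture_doc()
  bad$mentions$text[2] <- "20\nmg"
  expect_error(write_standoff(bad), class = "relex_validation_error")
})

test_that("standoff round-trip is the identity on random synthetic documents", {
  corpus <- fixture_corpus(n_docs = 100, relations_per_doc = 5, seed = 123)
  docs <- c(corpus$train, corpus$dev, corpus$test)
  expect_length(docs, 100)
  for (doc in docs) {
    so <- write_standoff(doc)
    back <- read_standoff(so$text, so$ann, doc_id = doc$doc_id)
    expect_equal(back$mentions, doc$mentions)
    expect_equal(back$relations, doc$relations)
    expect_equal(back$tokens, doc$tokens)
  }
})

test_that("document validation enforces schema and ordering invariants", {
  doc <- fixture_doc()
  # OtherSS in a relation
  bad <- doc
  bad$mentions$etype[6] <- "OtherSS"
  expect_error(validate_document(bad), class = "relex_validation_error")
  # arguments out of document order
  bad2 <- doc
  bad2$relations$left_id[1] <- "T2"
  bad2$relations$right_id[1] <- "T1"
  expect_error(validate_document(bad2), class = "relex_validation_error")
  # schema violation: Severity label on a Medication-Dosage pair
  bad3 <- doc
  bad3$relations$label[1] <- "Severity"
  expect_error(validate_document(bad3), class = "relex_validation_error")
  # duplicate positive relation
  bad4 <- doc
  bad4$relations <- rbind(bad4$relations, bad4$relations[1, ])
  bad4$relations$id[5] <- "R9"
  expect_error(validate_document(bad4), class = "relex_validation_error")
})

test_that("token distance matches its definition, is symmetric, adjacency gives 0", {
  doc <- fixture_doc()
  # "aspirin" and "20 mg" are adjacent
  expect_equal(token_distance(doc, "T1", "T2"), 0L)
  # "aspirin" .. "po": "20 mg" spans 2 tokens between
  expect_equal(token_distance(doc, "T1", "T3"), 2L)
  expect_equal(token_distance(doc, "T3", "T1"), 2L)
  expect_error(token_distance(doc, "T1", "T1"), class = "relex_overlap_error")
})

test_that("token distance equals brute-force enumeration on a long fixture", {
  surf <- paste0("w", 1:50)
  text <- paste(surf, collapse = " ")
  tokens <- tokenize(text)
  set.seed(4)
  starts <- sort(sample(seq(0, 48, by = 2), 10))
  mentions <- data.frame(
    id = paste0("T", seq_along(starts)), etype = "Medication",
    first_token = starts, last_token = starts + 1L,
    text = vapply(starts, function(s) paste(surf[s + 1:2], collapse = " "),
                  character(1)),
    stringsAsFactors = FALSE
  )
  doc <- relex_document("brute", text, tokens, mentions)
  for (i in 1:9) for (j in (i + 1):10) {
    a <- mentions[i, ]; b <- mentions[j, ]
    brute <- sum(seq(0, 49) > a$last_token & seq(0, 49) < b$first_token)
    expect_equal(token_distance(doc, a$id, b$id), brute)
    expect_equal(token_distance(doc, b$id, a$id), brute)
  }
})

test_that("mentions_between counts fully enclosed mentions symmetrically", {
  doc <- fixture_doc()
  expect_equal(mentions_between(doc, "T1", "T2"), 0L)
  # between "aspirin" (tok 0) and "severe" (tok 6) lie T2, T3, T4
  expect_equal(mentions_between(doc, "T1", "T5"), 3L)
  expect_equal(mentions_between(doc, "T5", "T1"), 3L)
  # partial overlap with the gap does not count: between T2 (1-2) and T5 (6)
  expect_equal(mentions_between(doc, "T2", "T5"), 2L)
})

test_that("embedding tables load, enforce dimensions, and default unknowns", {
  content <- "2 3\nalpha 1 2 3\nbeta 0.5 0 -1"
  tab <- load_embeddings(content)
  expect_equal(tab$dimension, 3)
  expect_equal(nrow(tab$vectors), 2)
  expect_equal(as.numeric(emb_lookup(tab, "beta")), c(0.5, 0, -1))
  expect_equal(as.numeric(emb_lookup(tab, "missing")), c(0, 0, 0))
  expect_error(load_embeddings("2 3\nalpha 1 2\nbeta 1 2 3"),
               class = "relex_format_error")
  expect_warning(load_embeddings("2 2\na 1 2\na 3 4"), "duplicate")
})

test_that("Brown paths load and prefix features truncate correctly", {
  paths <- load_brown_paths("0010\taspirin\t57\n01\tmg\t12")
  expect_equal(unname(unclass(paths)["aspirin"]), "0010")
  expect_error(load_brown_paths("01a2\tword\t3"), class = "relex_format_error")

  paths2 <- load_brown_paths("001011\tdrug\t5")
  expect_setequal(brown_prefixes("drug", paths2, c(4, 6)), c("0010", "001011"))
  expect_equal(brown_prefixes("mg", paths, 4), "01")
  expect_length(brown_prefixes("unseen", paths), 0)
})

test_that("the dictionary tagger maps words to semantic types", {
  tg <- dict_tagger(data.frame(word = c("aspirin", "aspirin", "nausea"),
                               type = c("pharm", "nsaid", "symptom")))
  tags <- tag_words(tg, c("Aspirin", "nausea", "unknown"))
  expect_setequal(tags[[1]], c("pharm", "nsaid"))
  expect_equal(tags[[2]], "symptom")
  expect_length(tags[[3]], 0)
})
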