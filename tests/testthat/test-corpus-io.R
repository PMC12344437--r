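# Document model, tokenisation, sentence splitting, BioC round trips and
# context-window construction.

test_that("document invariants are enforced", {
  expect_error(fix_doc("short", list(list(0, 99, "trait"))), "out of range")
  expect_error(
    tm_document("d", "Tipula", entity_table(0L, 6L, "arthropod",
                                            entity_id = "e1",
                                            text = "Xxxxxx")),
    "surface mismatch")
  d <- fix_doc("Tipula legs", list(list(0, 6, "arthropod"), list(7, 11, "trait")))
  expect_error(
    tm_document(d$doc_id, d$text, d$entities,
                data.frame(head = "e1", tail = "e2", rtype = "hasValue")),
    "inconsistent")
  ok <- tm_document(d$doc_id, d$text, d$entities,
                    data.frame(head = "e1", tail = "e2", rtype = "hasTrait"))
  expect_s3_class(ok, "tm_document")
})

test_that("tokenizer splits edge punctuation but keeps decimals and hyphens", {
  toks <- tokenize("Body length 56.6 mm (holotype), brownish-yellow.")
  expect_equal(toks$token,
               c("Body", "length", "56.6", "mm", "(", "holotype", ")", ",",
                 "brownish-yellow", "."))
  # spans slice back to the surfaces
  expect_equal(substr(rep("Body length 56.6 mm (holotype), brownish-yellow.",
                          nrow(toks)), toks$start + 1L, toks$end),
               toks$token)
  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(nrow(tokenize("   ")), 0L)
})

test_that("sentence splitter guards taxonomic abbreviations", {
  expect_equal(nrow(split_sentences("A. B.")), 1L)
  s <- split_sentences("First. Second.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$start, c(0L, 7L))
  s <- split_sentences("T. oleracea is large. Length 5 mm.")
  expect_equal(nrow(s), 2L)
  # "T." must not end a sentence; the real boundary is after "large."
  expect_equal(s$end[1], 21L)
  expect_equal(nrow(split_sentences("")), 0L)
  # guard list entries
  expect_equal(nrow(split_sentences("Tipula sp. nov. Descriptions follow.")), 1L)
})

test_that("sentence spans cover all non-whitespace text", {
  corpus <- generate_corpus(sim_config(seed = 11, n_docs = 3))
  for (d in corpus$documents) {
    s <- split_sentences(d$text)
    expect_true(all(s$start < s$end))
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))  # ordered, no overlap
    covered <- unlist(Map(seq, s$start + 1L, s$end))
    gaps <- setdiff(seq_len(nchar(d$text)), covered)
    expect_true(all(grepl("^\\s$", strsplit(d$text, "")[[1]][gaps])))
  }
})

test_that("empty BioC collection round-trips to an empty list", {
  f <- withr::local_tempfile(fileext = ".json")
  write_bioc_collection(list(), f)
  expect_equal(read_bioc_collection(f), list())
})

test_that("BioC passage offsets are rebased by concatenation", {
  # two passages of lengths 20 and 15; an annotation at passage-2 local
  # offset (0,5) lands at global (21,26) with the "\n" separator
  p1 <- "aaaaaaaaaaaaaaaaaaaa"  # 20 chars
  p2 <- "bbbbb bbbbb bbb"       # 15 chars
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(documents = list(list(
    id = "d1",
    passages = list(
      list(offset = 0L, text = p1, annotations = list(), relations = list()),
      list(offset = 20L, text = p2, relations = list(),
           annotations = list(list(
             id = "e1", infons = list(type = "trait"), text = "bbbbb",
             locations = list(list(offset = 20L, length = 5L)))))
    )))), f, auto_unbox = TRUE)
  docs <- read_bioc_collection(f)
  expect_length(docs, 1L)
  expect_equal(docs[[1]]$entities$start, 21L)
  expect_equal(docs[[1]]$entities$end, 26L)
  expect_equal(docs[[1]]$entities$surface, "bbbbb")
  expect_equal(docs[[1]]$text, paste(p1, p2, sep = "\n"))
})

test_that("BioC round trip is lossless including qualifiers and relations", {
  corpus <- generate_corpus(sim_config(seed = 3, n_docs = 3,
                                       density_qualifier = 1.5))
  docs <- corpus$documents
  docs[[1]]$split_tag <- "TRAIN-GOLD"
  f <- withr::local_tempfile(fileext = ".json")
  write_bioc_collection(docs, f)
  back <- read_bioc_collection(f)
  expect_length(back, length(docs))
  for (i in seq_along(docs)) {
    expect_equal(back[[i]]$text, docs[[i]]$text)
    expect_equal(back[[i]]$entities, docs[[i]]$entities)
    expect_equal(back[[i]]$relations, docs[[i]]$relations)
    expect_equal(back[[i]]$split_tag, docs[[i]]$split_tag)
  }
  expect_true(any(unlist(lapply(docs, function(d) d$entities$etype)) ==
                    "qualifier"))
  expect_true(any(unlist(lapply(docs, function(d) d$relations$rtype)) ==
                    "hasQualifier"))
})

test_that("malformed BioC JSON raises a format error", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(read_bioc_collection(f), "malformed")
})

test_that("context windows respect the sentence bound and gold labels", {
  # pair in the same sentence
  d <- fix_doc("Tipula legs are long.",
               list(list(0, 6, "arthropod"), list(7, 11, "trait")))
  d <- tm_document(d$doc_id, d$text, d$entities,
                   data.frame(head = "e1", tail = "e2", rtype = "hasTrait"))
  w <- build_context_windows(d)
  expect_equal(nrow(w), 1L)
  expect_equal(w$sent_first, w$sent_last)
  expect_equal(w$label, "hasTrait")
  expect_equal(substr(w$text, w$head_start + 1L, w$head_end), "Tipula")
  expect_equal(substr(w$text, w$tail_start + 1L, w$tail_end), "legs")

  # arthropod in sentence 1, trait in sentence 9: no window at bound 6
  far <- paste(c("Tipula here.", rep("Filler words now.", 7), "The femur there."),
               collapse = " ")
  d2 <- fix_doc(far, list(list(0, 6, "arthropod"),
                          list(regexpr("femur", far) - 1,
                               regexpr("femur", far) + 4, "trait")))
  expect_equal(nrow(build_context_windows(d2, max_sentences = 6L)), 0L)
  expect_equal(nrow(build_context_windows(d2, max_sentences = 9L)), 1L)
})

test_that("candidate windows match a brute-force pair enumeration", {
  corpus <- generate_corpus(sim_config(seed = 21, n_docs = 2))
  for (d in corpus$documents) {
    w <- build_context_windows(d, max_sentences = 6L)
    # independent enumeration
    sents <- split_sentences(d$text)
    e <- d$entities
    esent <- vapply(e$start, function(p) {
      hits <- which(sents$start <= p & p < sents$end)
      hits[1]
    }, 0L)
    expected <- 0L
    pos <- 0L
    for (i in seq_len(nrow(e))) for (j in seq_len(nrow(e))) {
      tp <- paste(e$etype[i], e$etype[j])
      if (!tp %in% c("arthropod trait", "trait value", "arthropod qualifier"))
        next
      if (abs(esent[i] - esent[j]) + 1L <= 6L) {
        expected <- expected + 1L
        g <- which(d$relations$head == e$entity_id[i] &
                     d$relations$tail == e$entity_id[j])
        if (length(g)) pos <- pos + 1L
      }
    }
    expect_equal(nrow(w), expected)
    expect_equal(sum(w$label != "none"), pos)
    # every positive window's label is a gold relation
    expect_true(all(w$label %in% c("none", "hasTrait", "hasValue",
                                   "hasQualifier")))
  }
})

test_that("long-range context clips, merges, and preserves surfaces", {
  # far apart: context length = 2*(flank + entity length) + separator
  filler <- paste(rep("x", 3000), collapse = "")
  text <- paste0("Tipula", filler, "femur")
  d <- fix_doc(text, list(list(0, 6, "arthropod"),
                          list(nchar(text) - 5, nchar(text), "trait")))
  w <- build_long_range_context(d, "e1", "e2", flank = 500L)
  sep_len <- nchar(" [SEP] ")
  expect_equal(nchar(w$text), (500 + 6) + sep_len + (500 + 5))
  expect_equal(substr(w$text, w$head_start + 1L, w$head_end), "Tipula")
  expect_equal(substr(w$text, w$tail_start + 1L, w$tail_end), "femur")
  # entity at document start: left flank truncated at 0
  expect_equal(w$head_start, 0L)

  # entities 100 chars apart with flank 500: one merged slice, both inside
  text2 <- paste0("Tipula", paste(rep("y", 100), collapse = ""), "femur",
                  paste(rep("z", 2000), collapse = ""))
  d2 <- fix_doc(text2, list(list(0, 6, "arthropod"), list(106, 111, "trait")))
  w2 <- build_long_range_context(d2, "e1", "e2", flank = 500L)
  expect_false(grepl("[SEP]", w2$text, fixed = TRUE))
  expect_equal(substr(w2$text, w2$tail_start + 1L, w2$tail_end), "femur")
  expect_lte(nchar(w2$text), 2 * (500 + 6) + sep_len)
  expect_error(build_long_range_context(d2, "e1", "e1"), "invalid pair")
})
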