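# Candidate generation, none-class balancing, inline tags, proximity
# baseline.

test_that("candidate enumeration with gold labels", {
  expect_equal(nrow(generate_candidates(fix_doc("Nothing to pair here."))), 0L)
  # 1 arthropod, 2 traits, 1 gold hasTrait -> 2 candidates, one positive
  text <- "Tipula has legs and wings."
  d <- fix_doc(text, list(list(0, 6, "arthropod"), list(11, 15, "trait"),
                          list(20, 25, "trait")))
  d <- tm_document(d$doc_id, d$text, d$entities,
                   data.frame(head = "e1", tail = "e2", rtype = "hasTrait"))
  cands <- generate_candidates(d)
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$label, c("hasTrait", "none"))
})

test_that("none-class balancing follows the majority-positive cap", {
  mk <- function(labels) data.frame(label = labels,
                                    id = seq_along(labels),
                                    stringsAsFactors = FALSE)
  # 10 none + 4 hasValue + 2 hasTrait -> 4 none kept, 10 rows total
  cands <- mk(c(rep("none", 10), rep("hasValue", 4), rep("hasTrait", 2)))
  out <- balance_none_class(cands, seed = 42L)
  expect_equal(sum(out$label == "none"), 4L)
  expect_equal(nrow(out), 10L)
  expect_equal(sum(out$label == "hasValue"), 4L)  # positives untouched
  expect_equal(sum(out$label == "hasTrait"), 2L)
  # already balanced: no-op
  c2 <- mk(c(rep("none", 3), rep("hasValue", 5)))
  expect_equal(balance_none_class(c2, 1L), c2)
  # no positives: zero none kept
  c3 <- mk(rep("none", 5))
  expect_equal(nrow(balance_none_class(c3, 1L)), 0L)
  # determinism contract
  expect_equal(balance_none_class(cands, 7L), balance_none_class(cands, 7L))
  sizes <- vapply(1:5, function(s) nrow(balance_none_class(cands, s)), 0L)
  expect_true(all(sizes == 10L))
})

test_that("inline tags are well-formed and invertible", {
  text <- "Tipula has long legs."
  d <- fix_doc(text, list(list(0, 6, "arthropod"), list(16, 20, "trait")))
  w <- generate_candidates(d)
  tagged <- inject_inline_tags(w[1, ])
  expect_match(tagged, '<head type="arthropod">Tipula</head>')
  expect_match(tagged, '<tail type="trait">legs</tail>')
  back <- strip_inline_tags(tagged)
  expect_equal(back$text, w$text[1])
  expect_equal(back$head_start, w$head_start[1])
  expect_equal(back$tail_end, w$tail_end[1])
  # tail before head in the text still recovers both spans
  d2 <- fix_doc("legs of Tipula here.", list(list(8, 14, "arthropod"),
                                             list(0, 4, "trait")))
  w2 <- generate_candidates(d2)
  b2 <- strip_inline_tags(inject_inline_tags(w2[1, ]))
  expect_equal(b2$text, w2$text[1])
  expect_equal(b2$head_start, w2$head_start[1])
  expect_equal(b2$tail_start, w2$tail_start[1])
  # adjacent entities produce well-nested non-overlapping tags
  d3 <- fix_doc("Tipulalegs move.", list(list(0, 6, "arthropod"),
                                         list(6, 10, "trait")))
  w3 <- generate_candidates(d3)
  t3 <- inject_inline_tags(w3[1, ])
  expect_equal(strip_inline_tags(t3)$text, w3$text[1])
  # overlapping spans are rejected
  w_bad <- w3[1, ]
  w_bad$tail_start <- 3L
  expect_error(inject_inline_tags(w_bad), "overlap")
})

test_that("proximity baseline links nearest typed mentions", {
  d <- fix_doc("Tipula legs yellow.",
               list(list(0, 6, "arthropod"), list(7, 11, "trait"),
                    list(12, 18, "value")))
  rel <- predict_proximity_relations(d)
  expect_setequal(rel$rtype, c("hasTrait", "hasValue"))
  e <- d$entities
  ht <- rel[rel$rtype == "hasTrait", ]
  expect_equal(e$surface[match(ht$head, e$entity_id)], "Tipula")
  expect_equal(e$surface[match(ht$tail, e$entity_id)], "legs")
  hv <- rel[rel$rtype == "hasValue", ]
  expect_equal(e$surface[match(hv$head, e$entity_id)], "legs")
  expect_equal(e$surface[match(hv$tail, e$entity_id)], "yellow")

  # value with no trait in its sentence: nothing emitted
  d2 <- fix_doc("The femur is long. Measures 5.6 mm.",
                list(list(4, 9, "trait"), list(28, 34, "value")))
  rel2 <- predict_proximity_relations(d2)
  expect_equal(nrow(rel2[rel2$rtype == "hasValue", ]), 0L)

  # two traits before a value: the nearer one wins
  d3 <- fix_doc("The femur and tibia measure 5.6 mm.",
                list(list(4, 9, "trait"), list(14, 19, "trait"),
                     list(28, 34, "value")))
  rel3 <- predict_proximity_relations(d3)
  hv3 <- rel3[rel3$rtype == "hasValue", ]
  expect_equal(d3$entities$surface[match(hv3$head, d3$entities$entity_id)],
               "tibia")
})

test_that("proximity predictions are type-consistent and recall planted truth", {
  corpus <- generate_corpus(sim_config(seed = 31, n_docs = 5))
  for (d in corpus$documents) {
    pred <- predict_proximity_relations(d)
    e <- d$entities
    ht <- e$etype[match(pred$head, e$entity_id)]
    tt <- e$etype[match(pred$tail, e$entity_id)]
    expect_true(all(relation_type_for(ht, tt) == pred$rtype))
    # every tail has one head
    expect_false(anyDuplicated(pred$tail) > 0)
  }
  pred_docs <- lapply(corpus$documents, function(d) {
    d$relations <- predict_proximity_relations(d); d
  })
  rep <- relation_eval(corpus$documents, pred_docs)
  expect_true(all(rep$per_type$R == 1.0))
})

test_that("RE JSONL export round-trips fields", {
  d <- fix_doc("Tipula legs yellow.",
               list(list(0, 6, "arthropod"), list(7, 11, "trait")))
  cands <- generate_candidates(d)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_re_jsonl(cands, f)
  rec <- jsonlite::fromJSON(readLines(f)[1])
  expect_equal(rec$text, cands$text[1])
  expect_equal(rec$head$start, cands$head_start[1])
  expect_equal(rec$label, cands$label[1])
})
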