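# Span alignment and Cohen's kappa agreement under exact/tolerance matching.

test_that("alignment pairs identical sets exactly", {
  a <- entity_table(c(0L, 10L), c(5L, 15L), c("trait", "value"))
  al <- align_spans(a, a, mode = "exact")
  expect_equal(nrow(al$pairs), 2L)
  expect_true(all(al$pairs$kind == "exact"))
  expect_length(al$unmatched_a, 0L)
})

test_that("partial matching respects the per-boundary tolerance", {
  a <- entity_table(10L, 20L, "trait")
  b <- entity_table(12L, 22L, "trait")
  al4 <- align_spans(a, b, mode = "partial", tolerance = 4L)
  expect_equal(nrow(al4$pairs), 1L)
  expect_equal(al4$pairs$kind, "partial")
  al1 <- align_spans(a, b, mode = "partial", tolerance = 1L)
  expect_equal(nrow(al1$pairs), 0L)
  expect_equal(al1$unmatched_a, 1L)
  expect_equal(al1$unmatched_b, 1L)
})

test_that("matched pairs are non-decreasing in tolerance", {
  set.seed(123)
  a <- entity_table(start = sort(sample(0:200, 12)) * 3L,
                    end = sort(sample(0:200, 12)) * 3L + 8L,
                    etype = sample(c("trait", "value"), 12, replace = TRUE))
  b <- entity_table(start = pmax(0L, a$start + sample(-6:6, 12, replace = TRUE)),
                    end = a$end + sample(-6:6, 12, replace = TRUE),
                    etype = a$etype)
  counts <- vapply(0:8, function(tol)
    nrow(align_spans(a, b, mode = "partial", tolerance = tol)$pairs), 0L)
  expect_true(all(diff(counts) >= 0L))
})

test_that("kappa is 1 for identical annotations and symmetric in annotators", {
  a <- entity_table(c(0L, 10L, 20L), c(5L, 15L, 25L),
                    c("trait", "value", "arthropod"))
  k <- entity_kappa(a, a)
  expect_equal(k$kappa, 1.0)
  expect_equal(k$p_o, 1.0)
  b <- entity_table(c(0L, 12L, 40L), c(5L, 17L, 45L),
                    c("trait", "trait", "value"))
  expect_equal(entity_kappa(a, b)$kappa, entity_kappa(b, a)$kappa)
  expect_error(entity_kappa(a[0, ], a[0, ]), "undefined")
})

test_that("kappa reproduces the chance-corrected formula", {
  # 10 aligned units, contingency diag (4,4), off-diag (1,1):
  # p_o = 0.8, p_e = 0.5, kappa = 0.6
  types_a <- c(rep("trait", 4), rep("value", 4), "trait", "value")
  types_b <- c(rep("trait", 4), rep("value", 4), "value", "trait")
  s <- 10L * (0:9)
  a <- entity_table(s, s + 5L, types_a)
  b <- entity_table(s, s + 5L, types_b)
  k <- entity_kappa(a, b, mode = "exact")
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.6)
})

test_that("kappa equals an independent contingency computation", {
  # 12-unit fixture with two types and unmatched spans on both sides
  s_a <- c(0L, 10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L)
  a <- entity_table(s_a, s_a + 6L,
                    c("trait", "trait", "trait", "value", "value",
                      "value", "trait", "value", "trait", "trait"))
  s_b <- c(1L, 11L, 21L, 31L, 41L, 52L, 200L, 300L)
  b <- entity_table(s_b, s_b + 6L,
                    c("trait", "value", "trait", "value", "value",
                      "value", "trait", "value"))
  k <- entity_kappa(a, b, mode = "partial", tolerance = 4L)
  # brute-force oracle: align greedily by the same rule, then tabulate
  lab_a <- c("trait", "trait", "trait", "value", "value", "value",
             rep("trait", 1), "value", "trait", "trait",  # a's 10 units
             "none", "none")                              # b's unmatched
  lab_b <- c("trait", "value", "trait", "value", "value", "value",
             "none", "none", "none", "none",
             "trait", "value")
  n <- length(lab_a)
  cats <- union(lab_a, lab_b)
  tab <- table(factor(lab_a, cats), factor(lab_b, cats))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  expect_equal(k$p_o, p_o)
  expect_equal(k$p_e, p_e)
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))
})

test_that("unit conservation: 2*matched + unmatched = |a| + |b|", {
  corpus <- generate_corpus(sim_config(seed = 53, n_docs = 2))
  d <- corpus$documents[[1]]
  a <- d$entities
  # simulate a second annotator: jitter half the spans, drop a few
  b <- a[seq_len(nrow(a)) %% 4L != 0L, , drop = FALSE]
  b$start <- b$start + (seq_len(nrow(b)) %% 2L)
  b$surface <- NA_character_
  al <- align_spans(a, b, mode = "partial", tolerance = 4L)
  expect_equal(2L * nrow(al$pairs) + length(al$unmatched_a) +
                 length(al$unmatched_b), nrow(a) + nrow(b))
  # exact mode can only match fewer pairs
  al_ex <- align_spans(a, b, mode = "exact")
  expect_lte(nrow(al_ex$pairs), nrow(al$pairs))
})

test_that("relation agreement matches endpoints within tolerance", {
  d <- fix_doc("Tipula legs yellow.",
               list(list(0, 6, "arthropod"), list(7, 11, "trait"),
                    list(12, 18, "value")))
  d <- tm_document(d$doc_id, d$text, d$entities,
                   data.frame(head = c("e1", "e2"), tail = c("e2", "e3"),
                              rtype = c("hasTrait", "hasValue")))
  ra <- resolve_relations(d)
  expect_equal(relation_agreement(ra, ra)$kappa, 1.0)
  # same pairs, different type: pure disagreement units
  rb <- ra
  rb$rtype <- c("hasValue", "hasTrait")
  k <- relation_agreement(ra, rb)
  expect_lt(k$kappa, 1.0)
  expect_equal(unname(k$unit_counts["agreed"]), 0L)
})

test_that("annotator relation totals pool as in a two-expert fixture", {
  # annotator 1: 343 hasTrait + 343 hasValue; annotator 2: 210 + 198;
  # before matching the pooled units are 553 hasTrait and 541 hasValue
  mk_rel <- function(n_ht, n_hv, jitter) {
    i <- seq_len(n_ht + n_hv)
    data.frame(doc_id = "d",
               head_start = 20L * i + jitter, head_end = 20L * i + 6L + jitter,
               head_type = rep(c("arthropod", "trait"), c(n_ht, n_hv)),
               tail_start = 20L * i + 8L, tail_end = 20L * i + 14L,
               tail_type = rep(c("trait", "value"), c(n_ht, n_hv)),
               rtype = rep(c("hasTrait", "hasValue"), c(n_ht, n_hv)),
               stringsAsFactors = FALSE)
  }
  a <- mk_rel(343L, 343L, 0L)
  b <- mk_rel(210L, 198L, 2L)
  expect_equal(sum(c(a$rtype, b$rtype) == "hasTrait"), 553L)
  expect_equal(sum(c(a$rtype, b$rtype) == "hasValue"), 541L)
  k <- relation_agreement(a, b, tolerance = 4L)
  # unit conservation for relations
  matched <- sum(k$unit_counts[c("unmatched_a", "unmatched_b")])
  expect_equal(k$unit_counts[["unmatched_a"]] + k$unit_counts[["unmatched_b"]] +
                 2L * (sum(k$table) - matched), nrow(a) + nrow(b))
})
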