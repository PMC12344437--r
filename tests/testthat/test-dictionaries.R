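# Taxon and trait dictionary construction, synonym handling, surface index.

toy_checklist <- function() {
  data.frame(
    taxonID = c("RT", "A", "B", "C", "D"),
    parentNameUsageID = c(NA, "RT", "A", "A", "X"),
    scientificName = c("Arthropoda", "Tipula", "Tipula oleracea",
                       "Tipula bogus", "Orphanus lostus"),
    taxonomicStatus = c("accepted", "accepted", "accepted", "synonym",
                        "accepted"),
    taxonRank = c("phylum", "genus", "species", "species", "species"),
    stringsAsFactors = FALSE)
}

test_that("taxon dictionary keeps accepted taxa reachable from the root", {
  dict <- build_taxon_dictionary(toy_checklist(), root_id = "RT")
  expect_setequal(dict$concepts$concept_id, c("A", "B"))
  b <- dict$concepts[dict$concepts$concept_id == "B", ]
  expect_equal(b$lineage, "Tipula | Arthropoda")
  expect_equal(b$category, "species")
  a <- dict$concepts[dict$concepts$concept_id == "A", ]
  expect_equal(a$lineage, "Arthropoda")
})

test_that("taxon dictionary edge cases: empty table, schema, cycles, order", {
  empty <- build_taxon_dictionary(toy_checklist()[0, ], root_id = "RT")
  expect_equal(nrow(empty$concepts), 0L)
  expect_error(
    build_taxon_dictionary(toy_checklist()[, -3], root_id = "RT"),
    "missing column")
  cyc <- data.frame(
    taxonID = c("RT", "A", "B"),
    parentNameUsageID = c(NA, "B", "A"),
    scientificName = c("Root", "Aname", "Bname"),
    taxonomicStatus = "accepted",
    taxonRank = c("phylum", "genus", "species"), stringsAsFactors = FALSE)
  cyc$parentNameUsageID <- c(NA, "RT", "A")
  cyc <- rbind(cyc, data.frame(taxonID = "C", parentNameUsageID = "D",
                               scientificName = "Cname",
                               taxonomicStatus = "accepted",
                               taxonRank = "species"))
  cyc <- rbind(cyc, data.frame(taxonID = "D", parentNameUsageID = "C",
                               scientificName = "Dname",
                               taxonomicStatus = "accepted",
                               taxonRank = "species"))
  # C and D form a cycle unreachable from the root: simply excluded
  d1 <- build_taxon_dictionary(cyc, root_id = "RT")
  expect_setequal(d1$concepts$concept_id, c("A", "B"))
  # row order never matters
  shuf <- toy_checklist()[c(4, 2, 5, 1, 3), ]
  d2 <- build_taxon_dictionary(shuf, root_id = "RT")
  expect_equal(d2$concepts, build_taxon_dictionary(toy_checklist(), "RT")$concepts)
})

test_that("trait dictionary loads rows with case-insensitive synonym de-dup", {
  dict <- fix_trait_dict()
  expect_equal(nrow(dict$concepts), 3L)
  femur <- dict$concepts[dict$concepts$preferred_term == "femur", ]
  expect_equal(femur$synonyms[[1]], "hind femur")
  # empty synonym cell -> no synonyms, surface index still has the term
  wing <- dict$concepts[dict$concepts$preferred_term == "wing", ]
  expect_equal(length(wing$synonyms[[1]]), 0L)
  expect_true("wing" %in% dict$surface_index$surface)
  # "leg; legs; Legs" -> two distinct forms
  d2 <- load_trait_dictionary(data.frame(
    term = "leg", category = "morphology", trait_type = "count",
    synonyms = "leg; legs; Legs", source_uri = "http://x.org/leg"))
  expect_equal(d2$concepts$synonyms[[1]], c("leg", "legs"))
})

test_that("trait dictionary rejects unknown categories and duplicate ids", {
  expect_error(load_trait_dictionary(data.frame(
    term = "leg", category = "anatomy", trait_type = "", synonyms = "",
    source_uri = "u1")), "unknown trait category")
  expect_error(load_trait_dictionary(data.frame(
    term = c("a", "b"), category = "habitat", trait_type = "",
    synonyms = "", source_uri = c("u1", "u1"))), "duplicate concept_id")
})

test_that("synonym frequency filter counts whole tokens case-insensitively", {
  dict <- load_trait_dictionary(data.frame(
    term = "femur", category = "morphology", trait_type = "",
    synonyms = "Femur bone; thighbone", source_uri = "u1"))
  corpus <- list(fix_doc(paste(c(rep("the femur bone is long.", 12),
                                 rep("a thighbone twice.", 2)),
                               collapse = " ")))
  out <- filter_synonyms_by_frequency(dict, corpus, min_count = 10L)
  expect_equal(out$concepts$synonyms[[1]], "Femur bone")
  # preferred terms always survive, even in an empty corpus
  out2 <- filter_synonyms_by_frequency(dict, list(), min_count = 10L)
  expect_equal(length(out2$concepts$synonyms[[1]]), 0L)
  expect_true("femur" %in% out2$surface_index$surface)
  # min_count 0: unchanged
  expect_equal(filter_synonyms_by_frequency(dict, list(), 0L)$concepts,
               dict$concepts)
  # substrings never count: "femurs" is not a "femur" token
  dict3 <- load_trait_dictionary(data.frame(
    term = "x", category = "morphology", trait_type = "", synonyms = "femur",
    source_uri = "u3"))
  corp3 <- list(fix_doc(paste(rep("femurs", 20), collapse = " ")))
  out3 <- filter_synonyms_by_frequency(dict3, corp3, min_count = 10L)
  expect_equal(length(out3$concepts$synonyms[[1]]), 0L)
})

test_that("plural expansion follows the regular rule table and is idempotent", {
  dict <- load_trait_dictionary(data.frame(
    term = c("leg", "proboscis", "body", "patch"),
    category = "morphology", trait_type = "",
    synonyms = "", source_uri = paste0("u", 1:4)))
  out <- expand_plural_variants(dict)
  syn_of <- function(d, term)
    d$concepts$synonyms[[which(d$concepts$preferred_term == term)]]
  expect_equal(syn_of(out, "leg"), "legs")
  expect_equal(length(syn_of(out, "proboscis")), 0L)  # ends in s: no naive plural
  expect_equal(syn_of(out, "body"), "bodies")
  expect_equal(syn_of(out, "patch"), "patches")
  # idempotent
  out2 <- expand_plural_variants(out)
  expect_equal(out2$concepts, out$concepts)
  # taxon concepts untouched
  tx <- expand_plural_variants(fix_taxon_dict())
  expect_equal(tx$concepts, fix_taxon_dict()$concepts)
})

test_that("surface index covers exactly preferred terms plus synonyms", {
  dict <- expand_plural_variants(fix_trait_dict())
  want <- unlist(lapply(seq_len(nrow(dict$concepts)), function(i)
    c(dict$concepts$preferred_term[i], dict$concepts$synonyms[[i]])))
  expect_setequal(dict$surface_index$surface, want)
  # deterministic rebuild
  expect_equal(build_surface_index(dict$concepts), dict$surface_index)
})
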