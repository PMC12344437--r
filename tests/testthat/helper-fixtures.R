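# Shared fixture builders; everything is constructed in code.

# minimal document with typed entities at given spans
fix_doc <- function(text, spans = list(), relations = empty_relations(),
                    doc_id = "doc1", split_tag = NA_character_) {
  if (length(spans)) {
    ents <- entity_table(
      start = vapply(spans, function(s) as.integer(s[[1]]), 0L),
      end = vapply(spans, function(s) as.integer(s[[2]]), 0L),
      etype = vapply(spans, function(s) as.character(s[[3]]), ""),
      text = text)
  } else ents <- empty_entities()
  tm_document(doc_id, text, ents, relations, split_tag)
}

# tiny trait dictionary: femur (syn "hind femur"), leg (syn "legs"), wing
fix_trait_dict <- function() {
  load_trait_dictionary(data.frame(
    term = c("femur", "leg", "wing"),
    category = c("morphology", "morphology", "morphology"),
    trait_type = "length/width",
    synonyms = c("hind femur", "legs", ""),
    source_uri = c("http://x.org/t1", "http://x.org/t2", "http://x.org/t3"),
    stringsAsFactors = FALSE))
}

# tiny taxon dictionary with a genus and a binomial below it
fix_taxon_dict <- function() {
  build_taxon_dictionary(data.frame(
    taxonID = c("RT", "G1", "S1"),
    parentNameUsageID = c(NA, "RT", "G1"),
    scientificName = c("Arthropoda", "Tipula", "Tipula oleracea"),
    taxonomicStatus = "accepted",
    taxonRank = c("phylum", "genus", "species"),
    stringsAsFactors = FALSE), root_id = "RT")
}

# a document with valid but arbitrary annotation layers for count-driven
# summaries: n_ent entities per type, n_rel relations per type
fix_counts_doc <- function(doc_id, n_arth = 0L, n_trait = 0L, n_value = 0L,
                           n_hastrait = 0L, n_hasvalue = 0L,
                           split_tag = NA_character_) {
  n <- n_arth + n_trait + n_value
  stopifnot(n > 0L)
  text <- paste(rep("aa", n), collapse = " ")
  start <- 3L * (seq_len(n) - 1L)
  ents <- entity_table(start, start + 2L,
                       rep(c("arthropod", "trait", "value"),
                           c(n_arth, n_trait, n_value)),
                       text = text)
  arth_ids <- ents$entity_id[ents$etype == "arthropod"]
  trait_ids <- ents$entity_id[ents$etype == "trait"]
  value_ids <- ents$entity_id[ents$etype == "value"]
  rel <- empty_relations()
  if (n_hastrait > 0L)
    rel <- rbind(rel, data.frame(
      head = rep_len(arth_ids, n_hastrait),
      tail = rep_len(trait_ids, n_hastrait), rtype = "hasTrait"))
  if (n_hasvalue > 0L)
    rel <- rbind(rel, data.frame(
      head = rep_len(trait_ids, n_hasvalue),
      tail = rep_len(value_ids, n_hasvalue), rtype = "hasValue"))
  tm_document(doc_id, text, ents, rel, split_tag)
}
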