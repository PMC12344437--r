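# Entity recognition: a gazetteer tagger over the dictionaries (greedy
# longest match with tiered matching), a deterministic pattern grammar for
# value mentions (measurements, numeric lists, percentages, colours), a
# closed qualifier lexicon, and overlap resolution across layers.

QUALIFIER_LEXICON <- c("female", "male", "juvenile", "larva", "adult",
                       "nymph", "pupa")

COLOR_LEXICON <- c("yellow", "brown", "black", "white", "red", "green",
                   "blue", "grey", "gray", "orange", "purple", "pink",
                   "silvery", "golden", "ochre", "fuscous", "testaceous")

VALUE_UNITS <- c("mm", "cm", "µm", "μm", "km", "mg", "kg", "m", "g", "%")

#' Gazetteer tagging against a dictionary
#'
#' Greedy longest match over the token sequence: at each position the
#' longest dictionary phrase wins and matching resumes after it. Matching
#' tiers per phrase: exact surface, case-folded, then case-folded with the
#' final token plural-stripped. Single-token taxon surfaces are matched
#' case-sensitively only (taxon capitalisation is informative; "Tipula"
#' must not fire on "tipula" -- or common words on capitalised forms).
#' Matches emit entities typed by the concept kind (`taxon` -> `arthropod`,
#' `trait` -> `trait`) with `concept_id` set and score 1.0.
#'
#' @param doc A `tm_document`.
#' @param dict A `tm_dictionary` (taxa, traits, or both).
#' @return Entity table.
#' @export
tag_with_dictionary <- function(doc, dict) {
  stopifnot(inherits(doc, "tm_document"), inherits(dict, "tm_dictionary"))
  idx <- dict$surface_index
  if (!nrow(idx)) return(empty_entities())
  toks <- tokenize(doc$text)
  if (!nrow(toks)) return(empty_entities())
  # token-join every dictionary surface with the same tokenizer
  phrase_tokens <- lapply(idx$surface, function(s) tokenize(s)$token)
  plen <- lengths(phrase_tokens)
  keep <- plen > 0L
  idx <- idx[keep, , drop = FALSE]; phrase_tokens <- phrase_tokens[keep]
  plen <- plen[keep]
  exact_key <- vapply(phrase_tokens, paste, "", collapse = " ")
  fold_key <- tolower(exact_key)
  single_taxon <- idx$kind == "taxon" & plen == 1L
  maxlen <- max(plen)
  lookup <- function(span_toks) {
    k_exact <- paste(span_toks, collapse = " ")
    hit <- which(exact_key == k_exact)
    if (!length(hit)) {
      k_fold <- tolower(k_exact)
      hit <- which(fold_key == k_fold & !single_taxon)
      if (!length(hit)) {
        last <- span_toks[length(span_toks)]
        sing <- singularize(tolower(last))
        if (!is.na(sing)) {
          k_strip <- tolower(paste(c(span_toks[-length(span_toks)], sing),
                                   collapse = " "))
          hit <- which(fold_key == k_strip & !single_taxon)
        }
      }
    }
    if (!length(hit)) return(NA_character_)
    sort(unique(idx$concept_id[hit]))[1]
  }
  out <- list()
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(maxlen, n - i + 1L), 1L)) {
      cid <- lookup(toks$token[i:(i + len - 1L)])
      if (!is.na(cid)) {
        kind <- dict$concepts$kind[match(cid, dict$concepts$concept_id)]
        out[[length(out) + 1L]] <- data.frame(
          start = toks$start[i], end = toks$end[i + len - 1L],
          etype = if (kind == "taxon") "arthropod" else "trait",
          concept_id = cid, stringsAsFactors = FALSE)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (!length(out)) return(empty_entities())
  m <- do.call(rbind, out)
  entity_table(m$start, m$end, m$etype, text = doc$text,
               concept_id = m$concept_id, score = 1.0)
}

#' Pattern-based tagging of value mentions
#'
#' A deterministic grammar recognising: number + unit measurements
#' ("56.6 mm"), percentages, runs of two or more comma-separated numbers
#' (one span per run, as printed measurement series), bare numbers directly
#' after a measurement keyword (length/width/height/size), and colour terms
#' from a closed lexicon including `-ish` derivatives and hyphenated
#' compounds ("brownish-yellow"). Overlapping matches are resolved to
#' maximal spans. Bare location values ("China") are out of the grammar's
#' scope: no location gazetteer is shipped.
#'
#' @param doc A `tm_document`.
#' @param color_lexicon Base colour terms.
#' @return Entity table of `value` entities with score 1.0.
#' @export
tag_values <- function(doc, color_lexicon = COLOR_LEXICON) {
  text <- doc$text
  num <- "[0-9]+(?:\\.[0-9]+)?"
  unit_alt <- paste(sort(VALUE_UNITS, decreasing = TRUE), collapse = "|")
  col_unit <- paste0("(?:", paste(color_lexicon, collapse = "|"), ")(?:ish)?")
  patterns <- c(
    # numeric list: >= 2 comma-separated numbers, one span
    paste0(num, "(?:\\s*,\\s*", num, ")+"),
    # measurement or range with unit
    paste0(num, "(?:\\s*[–-]\\s*", num, ")?\\s*(?:", unit_alt,
           ")(?![A-Za-z])"),
    # colour compounds
    paste0("\\b", col_unit, "(?:-", col_unit, ")*\\b")
  )
  spans <- list()
  for (p in patterns) {
    m <- gregexpr(p, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    for (j in seq_along(m)) {
      spans[[length(spans) + 1L]] <-
        c(as.integer(m[j]) - 1L, as.integer(m[j]) - 1L + attr(m, "match.length")[j])
    }
  }
  # bare number in measurement context: keyword then a number with no unit
  ctx <- paste0("(?i)\\b(?:length|width|height|size|diameter)\\s+(", num, ")\\b")
  m <- gregexpr(ctx, text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    for (j in seq_along(m)) {
      spans[[length(spans) + 1L]] <- c(cs[j, 1] - 1L, cs[j, 1] - 1L + cl[j, 1])
    }
  }
  if (!length(spans)) return(empty_entities())
  tab <- unique(data.frame(start = vapply(spans, `[`, 0L, 1L),
                           end = vapply(spans, `[`, 0L, 2L)))
  # keep maximal spans within the value layer: longer wins, then leftmost
  tab <- tab[order(-(tab$end - tab$start), tab$start), , drop = FALSE]
  kept <- tab[0, ]
  for (i in seq_len(nrow(tab))) {
    if (!any(tab$start[i] < kept$end & tab$end[i] > kept$start))
      kept <- rbind(kept, tab[i, ])
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  entity_table(kept$start, kept$end, "value", text = text, score = 1.0)
}

#' Tag life-stage/sex qualifiers from a closed lexicon
#'
#' Whole-token, case-insensitive matches of the qualifier lexicon
#' (female, male, juvenile, larva, adult, nymph, pupa).
#'
#' @param doc A `tm_document`.
#' @param lexicon Qualifier terms.
#' @return Entity table of `qualifier` entities with score 1.0.
#' @export
tag_qualifiers <- function(doc, lexicon = QUALIFIER_LEXICON) {
  toks <- tokenize(doc$text)
  hit <- which(tolower(toks$token) %in% tolower(lexicon))
  if (!length(hit)) return(empty_entities())
  entity_table(toks$start[hit], toks$end[hit], "qualifier",
               text = doc$text, score = 1.0)
}

#' Merge annotation layers into an overlap-free set
#'
#' Overlaps are resolved deterministically: the longer span wins; ties go by
#' entity-type precedence arthropod > trait > value > qualifier; remaining
#' ties to the leftmost span. The result is independent of input order.
#' Entity ids are reassigned in document order.
#'
#' @param ... Entity tables (annotation layers).
#' @return One overlap-free entity table sorted by `start`.
#' @export
merge_annotations <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !is.data.frame(layers[[1]])) layers <- layers[[1]]
  all <- do.call(rbind, c(list(empty_entities()), layers))
  if (!nrow(all)) return(all)
  prec <- match(all$etype, ENTITY_TYPES)
  ord <- order(-(all$end - all$start), prec, all$start)
  all <- all[ord, , drop = FALSE]
  kept <- all[0, , drop = FALSE]
  for (i in seq_len(nrow(all))) {
    if (!any(all$start[i] < kept$end & all$end[i] > kept$start))
      kept <- rbind(kept, all[i, , drop = FALSE])
  }
  kept <- kept[order(kept$start, kept$end), , drop = FALSE]
  kept$entity_id <- paste0("e", seq_len(nrow(kept)))
  rownames(kept) <- NULL
  kept
}

#' Run every baseline tagger on a document
#'
#' Convenience wrapper: gazetteer tagging with the taxon and trait
#' dictionaries, value patterns and the qualifier lexicon, merged into one
#' overlap-free layer which replaces the document's entity layer.
#'
#' @param doc A `tm_document`.
#' @param taxon_dict,trait_dict `tm_dictionary` objects (either may be
#'   `NULL`).
#' @param values,qualifiers Logical switches for the pattern taggers.
#' @return The document with its entity layer replaced by the tagger output
#'   (gold relations are dropped, since they reference gold entity ids).
#' @export
tag_document <- function(doc, taxon_dict = NULL, trait_dict = NULL,
                         values = TRUE, qualifiers = TRUE) {
  layers <- list()
  if (!is.null(taxon_dict)) layers <- c(layers, list(tag_with_dictionary(doc, taxon_dict)))
  if (!is.null(trait_dict)) layers <- c(layers, list(tag_with_dictionary(doc, trait_dict)))
  if (values) layers <- c(layers, list(tag_values(doc)))
  if (qualifiers) layers <- c(layers, list(tag_qualifiers(doc)))
  tm_document(doc$doc_id, doc$text, merge_annotations(layers),
              split_tag = doc$split_tag)
}
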