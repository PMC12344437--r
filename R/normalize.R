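# Entity normalisation: link recognised surfaces to dictionary concept ids
# by tiered flexible matching, and summarise how much of the annotation
# layer maps to concepts (and how much of each dictionary is ever seen).

#' Normalise one surface form to a dictionary concept id
#'
#' Tiered flexible matching, first tier with a hit wins:
#' 1. exact surface against preferred terms;
#' 2. case-folded against preferred terms;
#' 3. case-folded and whitespace-collapsed against preferred terms;
#' 4. as 3 with the final token plural-stripped;
#' 5. case-folded, whitespace-collapsed against the synonym table (with
#'    plural stripping as fallback).
#' An ambiguous hit within a tier resolves to the lexicographically smallest
#' concept id and is flagged via the `"ambiguous"` attribute.
#'
#' @param surface Entity surface string (or an entity-table row's surface).
#' @param dict A `tm_dictionary`.
#' @return The concept id, or `NA_character_` when no tier matches.
#' @export
normalize_entity <- function(surface, dict) {
  stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface))
  idx <- dict$surface_index
  if (!nrow(idx)) return(NA_character_)
  pref <- idx[idx$is_preferred, , drop = FALSE]
  syn <- idx[!idx$is_preferred, , drop = FALSE]
  key <- norm_key(surface)
  key_toks <- strsplit(key, " ", fixed = TRUE)[[1]]
  sing <- singularize(key_toks[length(key_toks)])
  key_strip <- if (is.na(sing)) NA_character_ else
    paste(c(key_toks[-length(key_toks)], sing), collapse = " ")
  tiers <- list(
    pref$concept_id[pref$surface == surface],
    pref$concept_id[tolower(pref$surface) == tolower(surface)],
    pref$concept_id[pref$key == key],
    if (!is.na(key_strip)) pref$concept_id[pref$key == key_strip] else character(0),
    {
      h <- syn$concept_id[syn$key == key]
      if (!length(h) && !is.na(key_strip)) h <- syn$concept_id[syn$key == key_strip]
      h
    }
  )
  for (hits in tiers) {
    hits <- unique(hits)
    if (length(hits) == 1L) return(hits)
    if (length(hits) > 1L) {
      out <- sort(hits)[1]
      attr(out, "ambiguous") <- TRUE
      return(out)
    }
  }
  NA_character_
}

#' Normalise every entity of a document against dictionaries
#'
#' Sets `concept_id` on arthropod entities via the taxon dictionary and on
#' trait entities via the trait dictionary; other types are left alone.
#'
#' @param doc A `tm_document`.
#' @param taxon_dict,trait_dict `tm_dictionary` objects (either may be
#'   `NULL`).
#' @return The document with updated `concept_id` values.
#' @export
normalize_document <- function(doc, taxon_dict = NULL, trait_dict = NULL) {
  e <- doc$entities
  for (i in seq_len(nrow(e))) {
    d <- switch(e$etype[i], arthropod = taxon_dict, trait = trait_dict, NULL)
    if (is.null(d)) next
    cid <- normalize_entity(e$surface[i], d)
    e$concept_id[i] <- as.character(cid)
  }
  doc$entities <- e
  validate_document(doc)
  doc
}

#' Summarise entity-to-concept mapping
#'
#' Reports `m` (total annotated entities of the kind), `k` (how many carry a
#' concept id) and the mapped percentage. For traits, `k` is also broken
#' down by dictionary category (only possible after successful linking).
#'
#' @param entities Entity table (optionally with `doc_id`), all of one kind.
#' @param kind `"arthropod"` or `"trait"`.
#' @param dict Optional `tm_dictionary` used for the per-category breakdown.
#' @param digits Decimal places of the reported percentage (default 1; the
#'   conventional integer-percent report uses `digits = 0`).
#' @return List of class `tm_norm_summary`: `kind`, `m`, `k`,
#'   `percent_mapped`, and `per_category` for traits.
#' @export
summarize_normalization <- function(entities, kind, dict = NULL, digits = 1L) {
  stopifnot(kind %in% c("arthropod", "trait"))
  e <- entities[entities$etype == kind, , drop = FALSE]
  m <- nrow(e)
  mapped <- !is.na(e$concept_id)
  k <- sum(mapped)
  per_category <- NULL
  if (kind == "trait" && !is.null(dict)) {
    cat_of <- dict$concepts$category[match(e$concept_id[mapped],
                                           dict$concepts$concept_id)]
    per_category <- vapply(TRAIT_CATEGORIES,
                           function(cc) sum(cat_of == cc, na.rm = TRUE), 0L)
  }
  structure(list(kind = kind, m = m, k = k,
                 percent_mapped = if (m == 0L) 0 else round(100 * k / m, digits),
                 per_category = per_category),
            class = "tm_norm_summary")
}

#' @export
print.tm_norm_summary <- function(x, ...) {
  cat(sprintf("%s normalisation: m = %d, k = %d (%.*f%% mapped)\n",
              x$kind, x$m, x$k, 1L, x$percent_mapped))
  if (!is.null(x$per_category))
    cat("  per category:",
        paste(names(x$per_category), x$per_category, sep = " = ",
              collapse = ", "), "\n")
  invisible(x)
}

#' Dictionary coverage by a corpus' linked entities
#'
#' `n` is the dictionary size, `l` the number of distinct concept ids that
#' were linked at least once; coverage is `100 * l / n`.
#'
#' @param entities Entity table with `concept_id` set where linked.
#' @param dict A `tm_dictionary` (or a subset of its concept table).
#' @param digits Decimal places of the percentage.
#' @return List of class `tm_coverage`: `n`, `l`, `percent_covered`.
#' @export
dictionary_coverage <- function(entities, dict, digits = 1L) {
  concepts <- if (inherits(dict, "tm_dictionary")) dict$concepts else dict
  ids <- unique(entities$concept_id[!is.na(entities$concept_id)])
  unknown <- setdiff(ids, concepts$concept_id)
  if (length(unknown))
    stop(sprintf("concept id '%s' not present in the dictionary", unknown[1]))
  n <- nrow(concepts); l <- length(ids)
  structure(list(n = n, l = l,
                 percent_covered = if (n == 0L) 0 else round(100 * l / n, digits)),
            class = "tm_coverage")
}

#' @export
print.tm_coverage <- function(x, ...) {
  cat(sprintf("dictionary coverage: n = %d, l = %d (%.1f%% covered)\n",
              x$n, x$l, x$percent_covered))
  invisible(x)
}

#' Count unique surface forms (case-folded)
#'
#' @param entities Entity table.
#' @return Number of distinct case-folded surfaces.
#' @export
unique_surface_count <- function(entities) {
  length(unique(tolower(entities$surface)))
}
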