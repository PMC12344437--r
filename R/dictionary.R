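# Dictionaries of normalisation targets: taxon concepts built from a
# Darwin-Core-style checklist, trait concepts loaded from a curated table.
# A dictionary holds an id-indexed concept table plus a surface index
# (every preferred term and synonym, with case-folded/whitespace-collapsed
# keys) that is rebuilt deterministically from the concepts.

TRAIT_CATEGORIES <- c("feeding ecology", "habitat", "morphology")

norm_key <- function(s) tolower(gsub("\\s+", " ", trimws(s)))

# regular English pluralisation; returns NA where no regular rule applies
# (words already ending in s are left alone -- irregulars like
# "proboscis" -> "proboscides" come via the synonyms column instead)
pluralize <- function(w) {
  vapply(w, function(x) {
    if (grepl("s$", x)) return(NA_character_)
    if (grepl("(x|z|ch|sh)$", x)) return(paste0(x, "es"))
    if (grepl("[^aeiou]y$", x)) return(sub("y$", "ies", x))
    paste0(x, "s")
  }, "", USE.NAMES = FALSE)
}

# inverse rule table; NA where the word does not look like a regular plural
singularize <- function(w) {
  vapply(w, function(x) {
    if (grepl("[^aeiou]ies$", x) && nchar(x) > 4L) return(sub("ies$", "y", x))
    if (grepl("(x|z|ch|sh)es$", x)) return(sub("es$", "", x))
    if (grepl("is$", x)) return(NA_character_)  # Latin singulars (proboscis)
    if (grepl("[^su]s$", x)) return(sub("s$", "", x))
    NA_character_
  }, "", USE.NAMES = FALSE)
}

new_dictionary <- function(concepts) {
  stopifnot(is.data.frame(concepts))
  if (anyDuplicated(concepts$concept_id))
    stop(sprintf("duplicate concept_id '%s'",
                 concepts$concept_id[anyDuplicated(concepts$concept_id)]))
  structure(list(concepts = concepts,
                 surface_index = build_surface_index(concepts)),
            class = "tm_dictionary")
}

#' Rebuild the surface index of a dictionary
#'
#' The index maps every preferred term and synonym to its concept id, with a
#' case-folded, whitespace-collapsed key alongside the verbatim surface.
#'
#' @param concepts Concept table (`concept_id`, `preferred_term`, `kind`,
#'   `category`, `synonyms` list column, ...).
#' @return Data frame `concept_id`, `surface`, `key`, `is_preferred`, `kind`.
#' @export
build_surface_index <- function(concepts) {
  if (!nrow(concepts))
    return(data.frame(concept_id = character(0), surface = character(0),
                      key = character(0), is_preferred = logical(0),
                      kind = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(concepts)), function(i) {
    syn <- concepts$synonyms[[i]]
    surf <- c(concepts$preferred_term[i], syn)
    data.frame(concept_id = concepts$concept_id[i], surface = surf,
               key = norm_key(surf),
               is_preferred = c(TRUE, rep(FALSE, length(syn))),
               kind = concepts$kind[i], stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows)
  idx[order(idx$concept_id, !idx$is_preferred, idx$surface), , drop = FALSE]
}

#' @export
print.tm_dictionary <- function(x, ...) {
  k <- table(x$concepts$kind)
  cat(sprintf("<tm_dictionary> %d concepts (%s); %d indexed surface forms\n",
              nrow(x$concepts),
              paste(names(k), k, sep = ": ", collapse = ", "),
              nrow(x$surface_index)))
  invisible(x)
}

#' Build a taxon dictionary from a Darwin-Core-style checklist
#'
#' Extracts every taxon with the accepted status that is hierarchically below
#' `root_id`, walking parent links over accepted rows only. Each concept
#' carries its ascending lineage of names (up to and including the root's
#' name). Non-accepted rows are excluded both as concepts and as lineage
#' steps, so taxa whose parent chain leaves the accepted set are dropped.
#'
#' @param checklist Data frame or delimited-file path with columns `taxonID`,
#'   `parentNameUsageID`, `scientificName`, `taxonomicStatus`, `taxonRank`.
#' @param root_id `taxonID` of the root taxon (itself not returned).
#' @param accepted_status Status value marking accepted rows.
#' @return A `tm_dictionary` of taxon concepts (`category` = rank, `lineage`
#'   = ancestor names joined by `" | "`, nearest first).
#' @export
build_taxon_dictionary <- function(checklist, root_id,
                                   accepted_status = "accepted") {
  tab <- if (is.character(checklist))
    utils::read.delim(checklist, stringsAsFactors = FALSE,
                      colClasses = "character") else checklist
  need <- c("taxonID", "parentNameUsageID", "scientificName",
            "taxonomicStatus", "taxonRank")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("checklist is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  empty <- new_dictionary(data.frame(
    concept_id = character(0), preferred_term = character(0),
    kind = character(0), category = character(0),
    trait_type = character(0), source_uri = character(0),
    lineage = character(0),
    synonyms = I(list()), stringsAsFactors = FALSE))
  if (!nrow(tab)) return(empty)
  tab <- tab[order(tab$taxonID), , drop = FALSE]  # row-order independence
  acc <- tab[tab$taxonomicStatus == accepted_status | tab$taxonID == root_id, ,
             drop = FALSE]
  # reachability downward from root through accepted rows
  kids <- split(acc$taxonID, acc$parentNameUsageID)
  name_of <- stats::setNames(acc$scientificName, acc$taxonID)
  rank_of <- stats::setNames(acc$taxonRank, acc$taxonID)
  parent_of <- stats::setNames(acc$parentNameUsageID, acc$taxonID)
  reach <- character(0)
  frontier <- root_id
  seen <- stats::setNames(logical(length(acc$taxonID)), acc$taxonID)
  if (root_id %in% names(seen)) seen[root_id] <- TRUE
  while (length(frontier)) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    nxt <- nxt[!seen[nxt]]
    if (anyNA(nxt)) nxt <- nxt[!is.na(nxt)]
    seen[nxt] <- TRUE
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  reach <- setdiff(reach, root_id)
  if (!length(reach)) return(empty)
  lineage <- vapply(reach, function(id) {
    path <- character(0); cur <- parent_of[[id]]; guard <- character(0)
    while (!is.na(cur) && cur %in% names(name_of)) {
      if (cur %in% guard)
        stop(sprintf("parent cycle involving taxonID(s): %s",
                     paste(c(guard, cur), collapse = ", ")))
      guard <- c(guard, cur)
      path <- c(path, name_of[[cur]])
      if (cur == root_id) break
      cur <- parent_of[[cur]]
    }
    paste(path, collapse = " | ")
  }, "", USE.NAMES = FALSE)
  concepts <- data.frame(
    concept_id = reach,
    preferred_term = unname(name_of[reach]),
    kind = "taxon",
    category = unname(rank_of[reach]),
    trait_type = NA_character_,
    source_uri = NA_character_,
    lineage = lineage,
    stringsAsFactors = FALSE
  )
  concepts$synonyms <- replicate(nrow(concepts), character(0), simplify = FALSE)
  concepts <- concepts[order(concepts$concept_id), , drop = FALSE]
  rownames(concepts) <- NULL
  new_dictionary(concepts)
}

#' Load a curated trait dictionary
#'
#' One concept per row. Synonyms are split on `;` (configurable), trimmed
#' and de-duplicated case-insensitively (first spelling kept). Categories
#' must be one of `feeding ecology`, `habitat`, `morphology`.
#'
#' @param table Data frame, or path to a TSV/CSV (or XLSX, if \pkg{readxl}
#'   is installed) file.
#' @param col_map Named mapping from the canonical column names (`term`,
#'   `category`, `trait_type`, `synonyms`, `source_uri`) to the file's.
#' @param synonym_sep Regular expression splitting the synonyms cell.
#' @return A `tm_dictionary` of trait concepts; concept ids are the source
#'   URIs (or `trait:<row>` when absent).
#' @export
load_trait_dictionary <- function(table,
                                  col_map = c(term = "term",
                                              category = "category",
                                              trait_type = "trait_type",
                                              synonyms = "synonyms",
                                              source_uri = "source_uri"),
                                  synonym_sep = ";") {
  tab <- table
  if (is.character(table)) {
    ext <- tolower(tools::file_ext(table))
    tab <- switch(ext,
      xlsx = {
        if (!requireNamespace("readxl", quietly = TRUE))
          stop("reading .xlsx requires the 'readxl' package; supply TSV/CSV instead")
        as.data.frame(readxl::read_excel(table))
      },
      csv = utils::read.csv(table, stringsAsFactors = FALSE),
      utils::read.delim(table, stringsAsFactors = FALSE)
    )
  }
  for (canon in c("term", "category")) {
    if (!col_map[[canon]] %in% names(tab))
      stop(sprintf("trait table is missing column '%s'", col_map[[canon]]))
  }
  if (!nrow(tab)) {
    concepts <- data.frame(
      concept_id = character(0), preferred_term = character(0),
      kind = character(0), category = character(0),
      trait_type = character(0), source_uri = character(0),
      lineage = character(0), stringsAsFactors = FALSE)
    concepts$synonyms <- list()
    return(new_dictionary(concepts))
  }
  get_col <- function(canon, default = NA_character_) {
    nm <- col_map[[canon]]
    if (!is.null(nm) && nm %in% names(tab)) as.character(tab[[nm]])
    else rep(default, nrow(tab))
  }
  term <- trimws(get_col("term"))
  category <- trimws(get_col("category"))
  bad <- which(!category %in% TRAIT_CATEGORIES)
  if (length(bad))
    stop(sprintf("row %d: unknown trait category '%s'", bad[1], category[bad[1]]))
  if (any(!nzchar(term)))
    stop(sprintf("row %d: empty term", which(!nzchar(term))[1]))
  uri <- get_col("source_uri")
  concept_id <- ifelse(is.na(uri) | !nzchar(uri),
                       paste0("trait:", seq_len(nrow(tab))), uri)
  syn_raw <- get_col("synonyms", default = "")
  synonyms <- lapply(seq_len(nrow(tab)), function(i) {
    s <- syn_raw[i]
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    parts <- trimws(strsplit(s, synonym_sep)[[1]])
    parts <- parts[nzchar(parts)]
    parts[!duplicated(tolower(parts))]
  })
  concepts <- data.frame(
    concept_id = concept_id, preferred_term = term, kind = "trait",
    category = category, trait_type = get_col("trait_type"),
    source_uri = uri, lineage = NA_character_, stringsAsFactors = FALSE)
  concepts$synonyms <- synonyms
  new_dictionary(concepts)
}

#' Count trait concepts per category
#'
#' @param dict A `tm_dictionary`.
#' @return Named integer vector over the trait categories.
#' @export
trait_category_counts <- function(dict) {
  tr <- dict$concepts[dict$concepts$kind == "trait", , drop = FALSE]
  vapply(TRAIT_CATEGORIES, function(cat) sum(tr$category == cat), 0L)
}

#' Drop rarely attested synonyms
#'
#' Removes synonyms (never preferred terms) whose case-insensitive
#' whole-token occurrence count across the corpus falls below `min_count`.
#' Multi-word synonyms are counted as consecutive token runs, not substrings.
#'
#' @param dict A `tm_dictionary`.
#' @param corpus List of `tm_document`s.
#' @param min_count Minimum corpus frequency a synonym must reach
#'   (default 10).
#' @return The filtered `tm_dictionary` (index rebuilt).
#' @export
filter_synonyms_by_frequency <- function(dict, corpus, min_count = 10L) {
  stopifnot(inherits(dict, "tm_dictionary"))
  if (min_count <= 0L) return(dict)
  doc_tokens <- lapply(corpus, function(d) tolower(tokenize(d$text)$token))
  count_phrase <- function(phrase) {
    toks <- tolower(tokenize(phrase)$token)
    n <- length(toks)
    if (n == 0L) return(0L)
    sum(vapply(doc_tokens, function(dt) {
      if (length(dt) < n) return(0L)
      if (n == 1L) return(sum(dt == toks))
      hits <- which(dt == toks[1])
      hits <- hits[hits + n - 1L <= length(dt)]
      sum(vapply(hits, function(h) all(dt[h:(h + n - 1L)] == toks), TRUE))
    }, 0L))
  }
  concepts <- dict$concepts
  concepts$synonyms <- lapply(concepts$synonyms, function(syn) {
    if (!length(syn)) return(syn)
    keep <- vapply(syn, count_phrase, 0L) >= min_count
    syn[keep]
  })
  new_dictionary(concepts)
}

#' Add regular plural/singular variants of trait surface forms
#'
#' For every trait preferred term and synonym, adds the regular English
#' plural or singular counterpart (`-s`, `-es` after sibilants, `-y` to
#' `-ies`) when it is not already present (case-insensitively). Words ending
#' in `s` are left alone and irregular plurals are expected to arrive via
#' the synonyms column. Taxon concepts are untouched. Idempotent.
#'
#' @param dict A `tm_dictionary`.
#' @return The expanded `tm_dictionary`.
#' @export
expand_plural_variants <- function(dict) {
  stopifnot(inherits(dict, "tm_dictionary"))
  concepts <- dict$concepts
  for (i in seq_len(nrow(concepts))) {
    if (concepts$kind[i] != "trait") next
    surf <- c(concepts$preferred_term[i], concepts$synonyms[[i]])
    variants <- c(pluralize(surf), singularize(surf))
    variants <- variants[!is.na(variants)]
    new <- variants[!tolower(variants) %in% tolower(surf)]
    new <- new[!duplicated(tolower(new))]
    if (length(new))
      concepts$synonyms[[i]] <- c(concepts$synonyms[[i]], new)
  }
  new_dictionary(concepts)
}
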