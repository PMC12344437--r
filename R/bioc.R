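# BioC JSON reading/writing. BioC stores a collection of documents, each a
# list of passages carrying text plus offset-based annotations and relations.
# On read, passages are concatenated (single "\n" separator) into one
# document text and all offsets are rebased into that global coordinate
# system; on write, each document is emitted as a single passage at offset 0,
# which makes the round trip exact.

#' Read a BioC JSON collection
#'
#' All passages of a BioC document are concatenated into one document text,
#' separated by a single newline, and annotation/relation offsets are rebased
#' globally. Entity annotations must carry an infon `type` with one of the
#' schema entity types; `concept_id` and `score` infons are preserved.
#'
#' @param path Path to a BioC JSON file.
#' @return List of `tm_document`s.
#' @export
read_bioc_collection <- function(path) {
  coll <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("malformed BioC JSON in '%s': %s",
                                     path, conditionMessage(e)))
  )
  docs <- coll$documents
  if (is.null(docs)) return(list())
  lapply(docs, bioc_document_to_tm)
}

bioc_document_to_tm <- function(bdoc) {
  doc_id <- as.character(bdoc$id %||% "")
  passages <- bdoc$passages %||% list()
  texts <- vapply(passages, function(p) as.character(p$text %||% ""), "")
  # new start of each passage in the concatenated text ("\n"-separated)
  new_starts <- integer(length(texts))
  pos <- 0L
  for (i in seq_along(texts)) {
    new_starts[i] <- pos
    pos <- pos + nchar(texts[i]) + 1L  # +1 for the separator
  }
  text <- paste(texts, collapse = "\n")
  ents <- list(); rels <- list()
  for (i in seq_along(passages)) {
    p <- passages[[i]]
    p_off <- as.integer(p$offset %||% 0L)
    for (a in p$annotations %||% list()) {
      loc <- a$locations[[1]]
      g_start <- as.integer(loc$offset) - p_off + new_starts[i]
      g_end <- g_start + as.integer(loc$length)
      if (g_start < 0L || g_end > nchar(text))
        stop(sprintf("document '%s': annotation offset (%d,%d) out of range",
                     doc_id, g_start, g_end))
      ents[[length(ents) + 1L]] <- data.frame(
        entity_id = as.character(a$id %||% paste0("e", length(ents) + 1L)),
        start = g_start, end = g_end,
        surface = as.character(a$text %||% substr(text, g_start + 1L, g_end)),
        etype = as.character(a$infons$type %||% NA_character_),
        concept_id = as.character(a$infons$concept_id %||% NA_character_),
        score = as.numeric(a$infons$score %||% NA_real_),
        stringsAsFactors = FALSE
      )
    }
    for (r in p$relations %||% list()) {
      nodes <- r$nodes
      roles <- vapply(nodes, function(x) as.character(x$role %||% ""), "")
      refs <- vapply(nodes, function(x) as.character(x$refid %||% ""), "")
      h <- refs[match("head", roles)]; t <- refs[match("tail", roles)]
      rels[[length(rels) + 1L]] <- data.frame(
        head = h, tail = t,
        rtype = as.character(r$infons$type %||% "none"),
        stringsAsFactors = FALSE
      )
    }
  }
  # document-level relations (some exporters put them there)
  for (r in bdoc$relations %||% list()) {
    nodes <- r$nodes
    roles <- vapply(nodes, function(x) as.character(x$role %||% ""), "")
    refs <- vapply(nodes, function(x) as.character(x$refid %||% ""), "")
    rels[[length(rels) + 1L]] <- data.frame(
      head = refs[match("head", roles)], tail = refs[match("tail", roles)],
      rtype = as.character(r$infons$type %||% "none"), stringsAsFactors = FALSE
    )
  }
  entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  split_tag <- as.character(bdoc$infons$split_tag %||% NA_character_)
  tm_document(doc_id, text, entities, relations, split_tag)
}

#' Write documents as a BioC JSON collection
#'
#' Serialisation twin of [read_bioc_collection()]: each document becomes one
#' passage at offset 0, preserving text, spans, entity types, concept ids,
#' scores, relations and split tags exactly, so
#' `read_bioc_collection(write_bioc_collection(docs, f))` reproduces `docs`.
#'
#' @param docs List of `tm_document`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bioc_collection <- function(docs, path) {
  bdocs <- lapply(docs, function(doc) {
    validate_document(doc)
    e <- doc$entities
    anns <- lapply(seq_len(nrow(e)), function(i) {
      infons <- list(type = e$etype[i])
      if (!is.na(e$concept_id[i])) infons$concept_id <- e$concept_id[i]
      if (!is.na(e$score[i])) infons$score <- e$score[i]
      list(id = e$entity_id[i], infons = infons,
           text = substr(doc$text, e$start[i] + 1L, e$end[i]),
           locations = list(list(offset = e$start[i],
                                 length = e$end[i] - e$start[i])))
    })
    r <- doc$relations
    rels <- lapply(seq_len(nrow(r)), function(i) {
      list(id = paste0("r", i), infons = list(type = r$rtype[i]),
           nodes = list(list(refid = r$head[i], role = "head"),
                        list(refid = r$tail[i], role = "tail")))
    })
    infons <- if (is.na(doc$split_tag)) structure(list(), names = character(0))
              else list(split_tag = doc$split_tag)
    list(id = doc$doc_id, infons = infons,
         passages = list(list(offset = 0L, text = doc$text,
                              annotations = anns, relations = rels)))
  })
  coll <- list(source = "traitmine", date = "", key = "",
               documents = bdocs)
  ok <- tryCatch({
    jsonlite::write_json(coll, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    TRUE
  }, error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                      conditionMessage(e))))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
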