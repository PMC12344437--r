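#' @keywords internal
"_PACKAGE"

ENTITY_TYPES <- c("arthropod", "trait", "value", "qualifier")
RELATION_TYPES <- c("hasTrait", "hasValue", "hasQualifier", "none")
SPLIT_TAGS <- c("TRAIN-GOLD", "TEST-GOLD")

#' Create an empty entity-annotation table
#'
#' Entities are stored as a data frame with one row per annotation. Character
#' offsets are 0-based, half-open `[start, end)`, counted in Unicode code
#' points, so `surface` is always `substr(text, start + 1, end)`.
#'
#' @return A zero-row data frame with columns `entity_id`, `start`, `end`,
#'   `surface`, `etype`, `concept_id`, `score`.
#' @export
empty_entities <- function() {
  data.frame(
    entity_id = character(0), start = integer(0), end = integer(0),
    surface = character(0), etype = character(0),
    concept_id = character(0), score = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Create an empty relation table
#'
#' @return A zero-row data frame with columns `head`, `tail`, `rtype`;
#'   `head`/`tail` reference `entity_id` values of the owning document.
#' @export
empty_relations <- function() {
  data.frame(head = character(0), tail = character(0), rtype = character(0),
             stringsAsFactors = FALSE)
}

#' Build an entity-annotation table
#'
#' @param start,end Integer vectors of 0-based, half-open character offsets.
#' @param etype Entity types; each must be one of `arthropod`, `trait`,
#'   `value`, `qualifier`.
#' @param text Optional document text used to fill in `surface`.
#' @param entity_id Optional ids; generated (`e1`, `e2`, ...) when missing.
#' @param concept_id Optional dictionary concept identifiers.
#' @param score Optional confidence scores in `[0, 1]`.
#' @return An entity table (see [empty_entities()]).
#' @export
entity_table <- function(start, end, etype, text = NULL, entity_id = NULL,
                         concept_id = NA_character_, score = NA_real_) {
  n <- length(start)
  if (n == 0L) return(empty_entities())
  if (is.null(entity_id)) entity_id <- paste0("e", seq_len(n))
  surface <- if (is.null(text)) NA_character_ else
    substr(rep(text, n), start + 1L, end)
  data.frame(
    entity_id = as.character(entity_id),
    start = as.integer(start), end = as.integer(end),
    surface = surface, etype = as.character(etype),
    concept_id = rep_len(as.character(concept_id), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
}

#' Construct an annotated document
#'
#' The unit flowing through every stage of the toolkit: plain text plus
#' character-offset entity and relation layers.
#'
#' @param doc_id Document identifier.
#' @param text Document text (one string).
#' @param entities Entity table (see [entity_table()]).
#' @param relations Relation table (see [empty_relations()]).
#' @param split_tag Optional `"TRAIN-GOLD"` or `"TEST-GOLD"` bookkeeping tag.
#' @return An object of class `tm_document`.
#' @examples
#' d <- tm_document("d1", "Tipula is large.",
#'                  entity_table(0L, 6L, "arthropod", text = "Tipula is large."))
#' d$entities$surface
#' @export
tm_document <- function(doc_id, text, entities = empty_entities(),
                        relations = empty_relations(), split_tag = NA_character_) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  doc <- structure(
    list(doc_id = doc_id, text = text, length = nchar(text),
         entities = entities, relations = relations,
         split_tag = split_tag),
    class = "tm_document"
  )
  validate_document(doc)
  doc
}

#' Validate a document's invariants
#'
#' Checks that every annotation span lies within the text, that surfaces
#' equal their text slices, that entity types and relation types belong to
#' the schema, and that relations reference existing entities with
#' type-consistent endpoints (arthropod-trait => hasTrait, trait-value =>
#' hasValue, arthropod-qualifier => hasQualifier).
#'
#' @param doc A `tm_document`.
#' @return `doc`, invisibly; stops with an informative error otherwise.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "tm_document"))
  e <- doc$entities
  if (nrow(e)) {
    bad <- e$start < 0L | e$end > doc$length | e$start >= e$end
    if (any(bad)) {
      stop(sprintf("document '%s': annotation span out of range: (%d,%d)",
                   doc$doc_id, e$start[which(bad)[1]], e$end[which(bad)[1]]))
    }
    if (anyDuplicated(e$entity_id))
      stop(sprintf("document '%s': duplicate entity_id", doc$doc_id))
    if (!all(e$etype %in% ENTITY_TYPES))
      stop(sprintf("document '%s': unknown entity type '%s'", doc$doc_id,
                   setdiff(e$etype, ENTITY_TYPES)[1]))
    sl <- substr(rep(doc$text, nrow(e)), e$start + 1L, e$end)
    off <- !is.na(e$surface) & sl != e$surface
    if (any(off))
      stop(sprintf("document '%s': surface mismatch at (%d,%d): '%s' != '%s'",
                   doc$doc_id, e$start[which(off)[1]], e$end[which(off)[1]],
                   e$surface[which(off)[1]], sl[which(off)[1]]))
    ok <- is.na(e$score) | (e$score >= 0 & e$score <= 1)
    if (!all(ok)) stop(sprintf("document '%s': score outside [0,1]", doc$doc_id))
  }
  r <- doc$relations
  if (nrow(r)) {
    if (!all(r$rtype %in% RELATION_TYPES))
      stop(sprintf("document '%s': unknown relation type '%s'", doc$doc_id,
                   setdiff(r$rtype, RELATION_TYPES)[1]))
    miss <- !(r$head %in% e$entity_id) | !(r$tail %in% e$entity_id)
    if (any(miss))
      stop(sprintf("document '%s': relation references missing entity",
                   doc$doc_id))
    ht <- e$etype[match(r$head, e$entity_id)]
    tt <- e$etype[match(r$tail, e$entity_id)]
    want <- relation_type_for(ht, tt)
    bad <- r$rtype != "none" & (is.na(want) | want != r$rtype)
    if (any(bad))
      stop(sprintf(
        "document '%s': relation type '%s' inconsistent with entity types %s->%s",
        doc$doc_id, r$rtype[which(bad)[1]], ht[which(bad)[1]], tt[which(bad)[1]]))
  }
  if (!is.na(doc$split_tag) && !doc$split_tag %in% SPLIT_TAGS)
    stop(sprintf("document '%s': unknown split_tag '%s'", doc$doc_id, doc$split_tag))
  invisible(doc)
}

#' Relation type implied by a (head, tail) entity-type pair
#'
#' @param head_type,tail_type Character vectors of entity types.
#' @return `"hasTrait"`, `"hasValue"`, `"hasQualifier"` or `NA` when the pair
#'   is not a schema pair.
#' @export
relation_type_for <- function(head_type, tail_type) {
  out <- rep(NA_character_, length(head_type))
  out[head_type == "arthropod" & tail_type == "trait"] <- "hasTrait"
  out[head_type == "trait" & tail_type == "value"] <- "hasValue"
  out[head_type == "arthropod" & tail_type == "qualifier"] <- "hasQualifier"
  out
}

#' @export
print.tm_document <- function(x, ...) {
  cat(sprintf("<tm_document '%s'> %d chars, %d entities, %d relations%s\n",
              x$doc_id, x$length, nrow(x$entities), nrow(x$relations),
              if (is.na(x$split_tag)) "" else paste0(" [", x$split_tag, "]")))
  invisible(x)
}

#' Collect the entity tables of a corpus into one table
#'
#' @param docs List of `tm_document`s.
#' @return Entity table with an extra leading `doc_id` column.
#' @export
corpus_entities <- function(docs) {
  if (length(docs) == 0L)
    return(cbind(data.frame(doc_id = character(0)), empty_entities()))
  do.call(rbind, lapply(docs, function(d) {
    if (nrow(d$entities) == 0L)
      return(cbind(data.frame(doc_id = character(0)), empty_entities()))
    cbind(data.frame(doc_id = d$doc_id, stringsAsFactors = FALSE), d$entities)
  }))
}

#' Resolve a document's relations to endpoint character spans
#'
#' @param doc A `tm_document`.
#' @param relations Optional relation table to resolve against the document's
#'   entities (defaults to the document's own relation layer).
#' @return Data frame with `doc_id`, head/tail spans and types, and `rtype`.
#' @export
resolve_relations <- function(doc, relations = doc$relations) {
  r <- relations
  if (nrow(r) == 0L)
    return(data.frame(doc_id = character(0), head_start = integer(0),
                      head_end = integer(0), head_type = character(0),
                      tail_start = integer(0), tail_end = integer(0),
                      tail_type = character(0), rtype = character(0),
                      stringsAsFactors = FALSE))
  e <- doc$entities
  hi <- match(r$head, e$entity_id); ti <- match(r$tail, e$entity_id)
  if (anyNA(hi) || anyNA(ti))
    stop(sprintf("document '%s': relation references missing entity", doc$doc_id))
  data.frame(doc_id = doc$doc_id,
             head_start = e$start[hi], head_end = e$end[hi],
             head_type = e$etype[hi],
             tail_start = e$start[ti], tail_end = e$end[ti],
             tail_type = e$etype[ti], rtype = r$rtype,
             stringsAsFactors = FALSE)
}

#' Resolve relations for every document in a corpus
#'
#' @param docs List of `tm_document`s.
#' @return Row-bound [resolve_relations()] tables.
#' @export
corpus_relations <- function(docs) {
  do.call(rbind, c(list(resolve_relations(tm_document("x", "x"))),
                   lapply(docs, resolve_relations)))
}
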