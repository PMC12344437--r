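# Relation-extraction context windows: for every typed candidate entity pair
# co-occurring within a bounded number of consecutive sentences, a window of
# text with both entity spans rebased into it; and a long-range variant that
# merges flanking slices around distant entities.

#' Build relation candidate context windows for a document
#'
#' Candidate pairs are all (arthropod, trait), (trait, value) and
#' (arthropod, qualifier) entity pairs whose two members lie within
#' `max_sentences` consecutive sentences. Each pair yields one window
#' covering the sentences from the first to the second entity; its label is
#' the gold relation type linking the pair if one exists, else `"none"`.
#'
#' @param doc A `tm_document`.
#' @param max_sentences Maximum number of consecutive sentences a pair may
#'   span (default 6).
#' @return Data frame with one row per candidate: `doc_id`, `head_id`,
#'   `tail_id`, `head_type`, `tail_type`, `sent_first`, `sent_last`, `text`,
#'   `head_start`, `head_end`, `tail_start`, `tail_end`, `label`.
#' @export
build_context_windows <- function(doc, max_sentences = 6L) {
  validate_document(doc)
  e <- doc$entities
  empty <- data.frame(doc_id = character(0), head_id = character(0),
                      tail_id = character(0), head_type = character(0),
                      tail_type = character(0), sent_first = integer(0),
                      sent_last = integer(0), text = character(0),
                      head_start = integer(0), head_end = integer(0),
                      tail_start = integer(0), tail_end = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (nrow(e) < 2L) return(empty)
  sents <- split_sentences(doc$text)
  if (!nrow(sents)) return(empty)
  esent <- sentence_of(sents, e$start)
  pairs <- rbind(
    expand.grid(h = which(e$etype == "arthropod"), t = which(e$etype == "trait")),
    expand.grid(h = which(e$etype == "trait"), t = which(e$etype == "value")),
    expand.grid(h = which(e$etype == "arthropod"),
                t = which(e$etype == "qualifier"))
  )
  if (!nrow(pairs)) return(empty)
  keep <- abs(esent[pairs$h] - esent[pairs$t]) + 1L <= max_sentences
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  gold_key <- paste(doc$relations$head, doc$relations$tail)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    h <- pairs$h[i]; t <- pairs$t[i]
    s1 <- min(esent[h], esent[t]); s2 <- max(esent[h], esent[t])
    w_start <- sents$start[s1]; w_end <- sents$end[s2]
    g <- match(paste(e$entity_id[h], e$entity_id[t]), gold_key)
    data.frame(
      doc_id = doc$doc_id, head_id = e$entity_id[h], tail_id = e$entity_id[t],
      head_type = e$etype[h], tail_type = e$etype[t],
      sent_first = s1, sent_last = s2,
      text = substr(doc$text, w_start + 1L, w_end),
      head_start = e$start[h] - w_start, head_end = e$end[h] - w_start,
      tail_start = e$start[t] - w_start, tail_end = e$end[t] - w_start,
      label = if (is.na(g)) "none" else doc$relations$rtype[g],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  bad <- out$head_start < 0L | out$tail_start < 0L |
    out$head_end > nchar(out$text) | out$tail_end > nchar(out$text)
  if (any(bad))
    stop(sprintf("document '%s': entity outside its sentence window", doc$doc_id))
  out
}

#' Build a long-range context for a distant entity pair
#'
#' Extracts the head and tail entities with `flank` surrounding characters
#' each (clipped to the document bounds). Overlapping or adjacent slices are
#' merged without duplication; otherwise the two slices are joined with
#' `separator`. Head and tail offsets are rebased so that they slice to the
#' entity surfaces in the returned text.
#'
#' @param doc A `tm_document`.
#' @param head,tail Entity ids (rows of `doc$entities`).
#' @param flank Characters of context either side of each entity
#'   (default 500).
#' @param separator String joining non-contiguous slices.
#' @return One-row data frame shaped like [build_context_windows()] output
#'   (without sentence columns).
#' @export
build_long_range_context <- function(doc, head, tail, flank = 500L,
                                     separator = " [SEP] ") {
  validate_document(doc)
  e <- doc$entities
  hi <- match(head, e$entity_id); ti <- match(tail, e$entity_id)
  if (is.na(hi) || is.na(ti)) stop("head/tail entity not found in document")
  if (hi == ti) stop("invalid pair: head and tail are the same entity")
  a_start <- max(0L, e$start[hi] - flank); a_end <- min(doc$length, e$end[hi] + flank)
  b_start <- max(0L, e$start[ti] - flank); b_end <- min(doc$length, e$end[ti] + flank)
  # order slices by position
  if (a_start <= b_start) {
    s1 <- c(a_start, a_end); s2 <- c(b_start, b_end)
  } else {
    s1 <- c(b_start, b_end); s2 <- c(a_start, a_end)
  }
  if (s2[1] <= s1[2]) {  # overlap or adjacency: one merged slice
    m_start <- s1[1]; m_end <- max(s1[2], s2[2])
    text <- substr(doc$text, m_start + 1L, m_end)
    h_off <- e$start[hi] - m_start; t_off <- e$start[ti] - m_start
    h_end <- e$end[hi] - m_start; t_end <- e$end[ti] - m_start
  } else {
    t1 <- substr(doc$text, s1[1] + 1L, s1[2])
    t2 <- substr(doc$text, s2[1] + 1L, s2[2])
    text <- paste0(t1, separator, t2)
    shift2 <- nchar(t1) + nchar(separator)
    rebase <- function(idx) {
      if (e$start[idx] >= s2[1]) c(e$start[idx] - s2[1] + shift2,
                                   e$end[idx] - s2[1] + shift2)
      else c(e$start[idx] - s1[1], e$end[idx] - s1[1])
    }
    h <- rebase(hi); t <- rebase(ti)
    h_off <- h[1]; h_end <- h[2]; t_off <- t[1]; t_end <- t[2]
  }
  out <- data.frame(
    doc_id = doc$doc_id, head_id = head, tail_id = tail,
    head_type = e$etype[hi], tail_type = e$etype[ti], text = text,
    head_start = h_off, head_end = h_end,
    tail_start = t_off, tail_end = t_end,
    label = NA_character_, stringsAsFactors = FALSE
  )
  stopifnot(substr(out$text, out$head_start + 1L, out$head_end) ==
              substr(doc$text, e$start[hi] + 1L, e$end[hi]),
            substr(out$text, out$tail_start + 1L, out$tail_end) ==
              substr(doc$text, e$start[ti] + 1L, e$end[ti]))
  out
}
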