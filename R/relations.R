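# Relation-extraction data construction (candidates, none-class balancing,
# inline entity tags, long-range contexts) and a deterministic proximity
# baseline predictor standing where a trained relation classifier would
# plug in.

#' Generate relation candidates for a document
#'
#' All typed entity pairs co-occurring within the sentence-window bound,
#' labelled with the gold relation type when one links the pair and
#' `"none"` otherwise (the negative class a relation classifier trains on).
#'
#' @param doc A `tm_document` whose entity layer is overlap-free.
#' @param max_sentences Window bound in consecutive sentences (default 6).
#' @return Candidate table (see [build_context_windows()]).
#' @export
generate_candidates <- function(doc, max_sentences = 6L) {
  build_context_windows(doc, max_sentences = max_sentences)
}

#' Balance the none class of a candidate set
#'
#' Down-samples `none`-labelled candidates uniformly at random (seeded) to
#' the count of the most frequent positive label; positive candidates are
#' never touched. With no positive labels, no `none` candidates are kept.
#'
#' @param cands Candidate table with a `label` column.
#' @param seed Integer seed driving the down-sampling.
#' @return The balanced candidate table (original row order preserved).
#' @export
balance_none_class <- function(cands, seed) {
  is_none <- cands$label == "none"
  pos_counts <- table(cands$label[!is_none])
  cap <- if (length(pos_counts)) max(pos_counts) else 0L
  none_idx <- which(is_none)
  if (length(none_idx) <= cap) return(cands)
  keep <- local_seed(seed, sample(none_idx, cap))
  cands[sort(c(which(!is_none), keep)), , drop = FALSE]
}

# evaluate `expr` under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Wrap candidate entities in inline XML tags
#'
#' The head span is wrapped in `<head type="...">...</head>` and the tail in
#' `<tail type="...">...</tail>`; all other text is unchanged, so stripping
#' the tags recovers the window text and offsets exactly.
#'
#' @param window One-row candidate table (rebased offsets).
#' @return The tagged text (single string).
#' @export
inject_inline_tags <- function(window) {
  stopifnot(nrow(window) == 1L)
  hs <- window$head_start; he <- window$head_end
  ts <- window$tail_start; te <- window$tail_end
  if (hs < te && ts < he) stop("invalid pair: head and tail spans overlap")
  text <- window$text
  pieces <- list(
    list(s = hs, e = he, open = sprintf('<head type="%s">', window$head_type),
         close = "</head>"),
    list(s = ts, e = te, open = sprintf('<tail type="%s">', window$tail_type),
         close = "</tail>")
  )
  pieces <- pieces[order(vapply(pieces, `[[`, 0L, "s"))]
  p1 <- pieces[[1]]; p2 <- pieces[[2]]
  paste0(substr(text, 1L, p1$s),
         p1$open, substr(text, p1$s + 1L, p1$e), p1$close,
         substr(text, p1$e + 1L, p2$s),
         p2$open, substr(text, p2$s + 1L, p2$e), p2$close,
         substr(text, p2$e + 1L, nchar(text)))
}

#' Strip inline entity tags
#'
#' Inverse of [inject_inline_tags()]: removes the `<head>`/`<tail>` tags and
#' returns the original text plus the recovered spans.
#'
#' @param tagged Tagged text.
#' @return List with `text`, `head_start`, `head_end`, `tail_start`,
#'   `tail_end`.
#' @export
strip_inline_tags <- function(tagged) {
  out <- list()
  text <- tagged
  # strip leftmost-first so recovered offsets are in final-text coordinates
  repeat {
    m <- regexpr('<(head|tail) type="[^"]*">', text, perl = TRUE)
    if (m == -1L) break
    role <- sub('^<(head|tail).*$', "\\1", regmatches(text, m))
    open_len <- attr(m, "match.length")
    s <- as.integer(m) - 1L
    close_tag <- sprintf("</%s>", role)
    cpos <- regexpr(close_tag, text, fixed = TRUE)
    e <- as.integer(cpos) - 1L - open_len
    text <- paste0(substr(text, 1L, s),
                   substr(text, s + open_len + 1L, e + open_len),
                   substr(text, e + open_len + nchar(close_tag) + 1L,
                          nchar(text)))
    out[[paste0(role, "_start")]] <- s
    out[[paste0(role, "_end")]] <- e
  }
  if (is.null(out$head_start) || is.null(out$tail_start))
    stop("tagged text lacks <head> or <tail> tags")
  c(list(text = text), out)
}

#' Proximity baseline relation predictor
#'
#' Deterministic nearest-mention rules: every value links to the nearest
#' preceding trait in its sentence (`hasValue`); every trait links to the
#' nearest arthropod within the sentence-window bound, preferring preceding
#' mentions (`hasTrait`); every qualifier links to the nearest preceding
#' arthropod in its sentence (`hasQualifier`). Each tail gets at most one
#' head. Serves as the deterministic stand-in where a trained relation
#' classifier would plug in.
#'
#' @param doc A `tm_document` with an overlap-free entity layer.
#' @param max_sentences Window bound for `hasTrait` links (default 6).
#' @return Relation table referencing `doc$entities` ids.
#' @export
predict_proximity_relations <- function(doc, max_sentences = 6L) {
  e <- doc$entities
  if (nrow(e) < 2L) return(empty_relations())
  sents <- split_sentences(doc$text)
  esent <- sentence_of(sents, e$start)
  rels <- list()
  link <- function(head_i, tail_i, rtype) {
    rels[[length(rels) + 1L]] <<- data.frame(
      head = e$entity_id[head_i], tail = e$entity_id[tail_i],
      rtype = rtype, stringsAsFactors = FALSE)
  }
  for (i in which(e$etype == "value")) {
    cand <- which(e$etype == "trait" & esent == esent[i] & e$end <= e$start[i])
    if (length(cand)) link(cand[which.max(e$end[cand])], i, "hasValue")
  }
  for (i in which(e$etype == "trait")) {
    arth <- which(e$etype == "arthropod")
    arth <- arth[abs(esent[arth] - esent[i]) + 1L <= max_sentences]
    if (!length(arth)) next
    pre <- arth[e$end[arth] <= e$start[i]]
    pick <- if (length(pre)) pre[which.max(e$end[pre])]
            else arth[which.min(e$start[arth])]
    link(pick, i, "hasTrait")
  }
  for (i in which(e$etype == "qualifier")) {
    cand <- which(e$etype == "arthropod" & esent == esent[i] &
                    e$end <= e$start[i])
    if (length(cand)) link(cand[which.max(e$end[cand])], i, "hasQualifier")
  }
  if (!length(rels)) return(empty_relations())
  do.call(rbind, rels)
}

#' Export candidates as relation-extraction JSON lines
#'
#' One JSON object per candidate: `doc_id`, `text`, `head`/`tail` (start,
#' end, type) and `label` -- the context-window exchange format a
#' model-based relation classifier consumes.
#'
#' @param cands Candidate table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_re_jsonl <- function(cands, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(cands))) {
    rec <- list(doc_id = cands$doc_id[i], text = cands$text[i],
                head = list(start = cands$head_start[i],
                            end = cands$head_end[i],
                            type = cands$head_type[i]),
                tail = list(start = cands$tail_start[i],
                            end = cands$tail_end[i],
                            type = cands$tail_type[i]),
                label = cands$label[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
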