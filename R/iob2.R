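# IOB2 / CoNLL conversion. A token-label sequence keeps token character
# spans alongside the tags so conversion back to character-offset entities
# is exact whenever entity boundaries are token-aligned.

iob_type <- function(etype) {
  c(arthropod = "Arthropod", trait = "Trait", value = "Value",
    qualifier = "Qualifier")[etype]
}
iob_etype <- function(type) {
  c(Arthropod = "arthropod", Trait = "trait", Value = "value",
    Qualifier = "qualifier")[type]
}

#' Convert a document's entity layer to an IOB2 token-label sequence
#'
#' Tokens are produced by [tokenize()] and grouped into sentences by
#' [split_sentences()]. Every token whose span intersects an entity receives
#' that entity's tag (`B-` on the first intersecting token, `I-` after); all
#' other tokens are `O`. Entity boundaries falling inside a token expand the
#' label to the whole token; the character-accurate span stays in the
#' annotation layer.
#'
#' @param doc A `tm_document` with non-overlapping entities (merge with
#'   [merge_annotations()] first).
#' @return An object of class `tm_iob`: list with `doc_id`, `tokens` (data
#'   frame `token`, `start`, `end`, `sentence`) and `labels`.
#' @export
entities_to_iob2 <- function(doc) {
  validate_document(doc)
  e <- doc$entities[order(doc$entities$start, doc$entities$end), , drop = FALSE]
  if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
    stop("overlapping entities; run merge_annotations() before IOB2 conversion")
  toks <- tokenize(doc$text)
  sents <- split_sentences(doc$text)
  toks$sentence <- if (nrow(toks)) sentence_of(sents, toks$start) else integer(0)
  labels <- rep("O", nrow(toks))
  for (i in seq_len(nrow(e))) {
    hit <- which(toks$start < e$end[i] & toks$end > e$start[i])
    if (!length(hit)) next
    labels[hit[1]] <- paste0("B-", iob_type(e$etype[i]))
    if (length(hit) > 1L)
      labels[hit[-1L]] <- paste0("I-", iob_type(e$etype[i]))
  }
  structure(list(doc_id = doc$doc_id, tokens = toks, labels = labels),
            class = "tm_iob")
}

#' Recover entity annotations from an IOB2 sequence
#'
#' Maximal `B-X I-X ...` runs become entities spanning from the first token's
#' start to the last token's end. Ill-formed input is repaired with
#' conlleval-compatible semantics: an orphan `I-X` (after `O`, after a tag of
#' a different type, or at sequence start) opens a new chunk.
#'
#' @param seq A `tm_iob` object.
#' @param text Optional document text used to fill entity surfaces.
#' @return An entity table.
#' @export
iob2_to_entities <- function(seq, text = NULL) {
  stopifnot(inherits(seq, "tm_iob"))
  ch <- iob_chunks(seq$labels, seq$tokens$sentence)
  if (!nrow(ch)) return(empty_entities())
  entity_table(start = seq$tokens$start[ch$first],
               end = seq$tokens$end[ch$last],
               etype = unname(iob_etype(ch$type)), text = text)
}

# chunk extraction with lenient repair; sentence vector (optional) forces
# chunk breaks at sentence boundaries
iob_chunks <- function(labels, sentence = NULL) {
  n <- length(labels)
  out <- list()
  cur_type <- NA_character_; cur_first <- NA_integer_
  flush <- function(i) {
    if (!is.na(cur_type))
      out[[length(out) + 1L]] <<- data.frame(
        type = cur_type, first = cur_first, last = i, stringsAsFactors = FALSE)
    cur_type <<- NA_character_
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    new_sent <- !is.null(sentence) && i > 1L && sentence[i] != sentence[i - 1L]
    if (new_sent) flush(i - 1L)
    if (lab == "O" || is.na(lab)) {
      flush(i - 1L)
    } else {
      pre <- substr(lab, 1L, 1L)
      typ <- substr(lab, 3L, nchar(lab))
      if (pre == "B" || is.na(cur_type) || typ != cur_type) {
        flush(i - 1L)                    # orphan I-X promoted to chunk start
        cur_type <- typ; cur_first <- i
      }
    }
  }
  flush(n)
  if (!length(out))
    return(data.frame(type = character(0), first = integer(0),
                      last = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write token-label sequences as a CoNLL file
#'
#' One `token<TAB>label` line per token, blank line between sentences, two
#' blank lines between documents.
#'
#' @param seqs A `tm_iob` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(seqs, path) {
  if (inherits(seqs, "tm_iob")) seqs <- list(seqs)
  blocks <- vapply(seqs, function(s) {
    if (!nrow(s$tokens)) return("")
    lines <- paste0(s$tokens$token, "\t", s$labels)
    paste(unlist(lapply(split(lines, s$tokens$sentence), paste, collapse = "\n")),
          collapse = "\n\n")
  }, "")
  writeLines(paste(blocks, collapse = "\n\n\n"), path)
  invisible(path)
}

#' Read a CoNLL file into token-label sequences
#'
#' Inverse of [write_conll()] up to character offsets: token spans are
#' re-derived by laying tokens out left to right, one space apart, sentence
#' per line-block (offsets are not stored in CoNLL).
#'
#' @param path CoNLL file path.
#' @return List of `tm_iob` objects (one per document block).
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE)
  doc_breaks <- which(lines == "")
  # split into documents on runs of >= 2 blank lines
  docs <- list(); cur <- character(0); blank_run <- 0L
  for (ln in c(lines, "", "")) {
    if (ln == "") {
      blank_run <- blank_run + 1L
      if (blank_run == 2L && length(cur)) { docs[[length(docs) + 1L]] <- cur; cur <- character(0) }
      if (blank_run < 2L) cur <- c(cur, ln)
    } else {
      blank_run <- 0L
      cur <- c(cur, ln)
    }
  }
  lapply(seq_along(docs), function(d) {
    lns <- docs[[d]]
    tok <- character(0); lab <- character(0); sent <- integer(0)
    s <- 1L
    for (ln in lns) {
      if (ln == "") { s <- s + 1L; next }
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      tok <- c(tok, parts[1]); lab <- c(lab, parts[2]); sent <- c(sent, s)
    }
    # normalise sentence numbering and lay out offsets
    sent <- match(sent, unique(sent))
    start <- integer(length(tok)); pos <- 0L
    for (i in seq_along(tok)) {
      start[i] <- pos
      pos <- pos + nchar(tok[i]) + 1L
    }
    structure(list(doc_id = paste0("conll_doc_", d),
                   tokens = data.frame(token = tok, start = start,
                                       end = start + nchar(tok),
                                       sentence = sent, stringsAsFactors = FALSE),
                   labels = lab),
              class = "tm_iob")
  })
}
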