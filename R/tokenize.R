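# Tokenisation and sentence splitting. Both operate on raw text and return
# 0-based, half-open character spans so downstream layers can always slice
# surfaces back out of the document.

# punctuation peeled off token edges; hyphens and internal dots are kept so
# "brownish-yellow" and "56.6" stay single tokens
TOKEN_EDGE_PUNCT <- c(".", ",", ";", ":", "(", ")", "[", "]", "\"", "'",
                      "—", "“", "”", "‘", "’")

# sentence-ender guards: never split after these words (genus abbreviations
# "T.", "sp. nov." etc.)
SENTENCE_GUARDS <- c("sp.", "spp.", "nov.", "cf.", "e.g.", "i.e.", "Fig.",
                     "fig.", "al.", "ca.")

#' Tokenise text into word spans
#'
#' Whitespace tokenisation followed by peeling leading/trailing punctuation
#' (`.,;:()[]"'` and typographic quotes/dashes) into separate one-character
#' tokens. Decimal numbers ("56.6") and hyphenated words ("brownish-yellow")
#' remain single tokens because only edge characters are peeled.
#'
#' @param text A single string.
#' @return Data frame with columns `token`, `start`, `end` (0-based,
#'   half-open spans into `text`).
#' @examples
#' tokenize("Body length 56.6 mm (holotype).")$token
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- data.frame(token = character(0), start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(out)
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  toks <- list()
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + lens[i]
    w <- substr(text, s + 1L, e)
    # peel leading punctuation
    while (nchar(w) > 1L && substr(w, 1L, 1L) %in% TOKEN_EDGE_PUNCT) {
      toks[[length(toks) + 1L]] <- c(substr(w, 1L, 1L), s, s + 1L)
      s <- s + 1L
      w <- substr(text, s + 1L, e)
    }
    trail <- character(0)
    while (nchar(w) > 1L && substr(w, nchar(w), nchar(w)) %in% TOKEN_EDGE_PUNCT) {
      trail <- c(substr(w, nchar(w), nchar(w)), trail)
      e <- e - 1L
      w <- substr(text, s + 1L, e)
    }
    toks[[length(toks) + 1L]] <- c(w, s, e)
    if (length(trail)) {
      for (j in seq_along(trail)) {
        toks[[length(toks) + 1L]] <- c(trail[j], e + j - 1L, e + j)
      }
    }
  }
  data.frame(token = vapply(toks, `[`, "", 1L),
             start = as.integer(vapply(toks, `[`, "", 2L)),
             end = as.integer(vapply(toks, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Split document text into sentence spans
#'
#' Rule-based splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and then a capital letter or digit. A guard list prevents
#' splitting after taxonomic and common abbreviations: any single capital
#' followed by a period (genus abbreviations such as "T.") and the closed set
#' "sp.", "spp.", "nov.", "cf.", "e.g.", "i.e.", "Fig.", "al.", "ca.".
#' Returned spans are trimmed to non-whitespace and, together, cover all
#' non-whitespace characters of the text.
#'
#' @param doc A `tm_document` or a single string.
#' @return Data frame with columns `start`, `end` (0-based, half-open).
#' @examples
#' split_sentences("T. oleracea is large. Length 5 mm.")
#' @export
split_sentences <- function(doc) {
  text <- if (inherits(doc, "tm_document")) doc$text else doc
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  ender <- which(chars %in% c(".", "!", "?"))
  boundaries <- integer(0)  # 1-based index of the sentence-final character
  for (p in ender) {
    if (p == n) next  # trailing text handled below
    nxt <- p + 1L
    # require whitespace then capital/digit
    q <- nxt
    while (q <= n && grepl("^\\s$", chars[q])) q <- q + 1L
    if (q == nxt || q > n) next          # no whitespace gap or only spaces left
    if (!grepl("^[A-Z0-9À-Ý]$", chars[q])) next
    if (chars[p] == ".") {
      # the word ending at p, period included
      ws <- p
      while (ws > 1L && !grepl("^\\s$", chars[ws - 1L])) ws <- ws - 1L
      word <- substr(text, ws, p)
      if (word %in% SENTENCE_GUARDS || grepl("^[A-Z]\\.$", word)) next
    }
    boundaries <- c(boundaries, p)
  }
  cuts <- c(0L, boundaries, n)  # segments (cuts[i], cuts[i+1]]
  spans <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    s0 <- cuts[i] + 1L; e0 <- cuts[i + 1L]  # 1-based inclusive
    seg <- substr(text, s0, e0)
    lead <- regmatches(seg, regexpr("^\\s*", seg))
    tail_ws <- regmatches(seg, regexpr("\\s*$", seg))
    s0 <- s0 + nchar(lead); e0 <- e0 - nchar(tail_ws)
    if (s0 > e0) next
    spans[[length(spans) + 1L]] <- c(s0 - 1L, e0)  # to 0-based half-open
  }
  if (!length(spans)) return(empty)
  data.frame(start = vapply(spans, `[`, 0L, 1L),
             end = vapply(spans, `[`, 0L, 2L))
}

# index of the sentence containing 0-based character offset `pos`
# (the sentence whose trimmed span contains it, else the nearest span
# starting after it; used to place entities whose start falls in the
# whitespace between sentences)
sentence_of <- function(sentences, pos) {
  vapply(pos, function(p) {
    hit <- which(sentences$start <= p & p < sentences$end)
    if (length(hit)) return(hit[1])
    after <- which(sentences$start > p)
    if (length(after)) after[1] else nrow(sentences)
  }, 0L)
}
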