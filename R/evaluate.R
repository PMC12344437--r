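# Scoring predicted annotations against gold: strict (character span +
# type exact match) and CoNLL-style (token-chunk match with lenient repair)
# entity metrics, relation metrics, and macro/weighted aggregation. The
# zero-division convention throughout is P = R = F = 0 when the denominator
# is 0.

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param P,R Precision and recall in `[0, 1]` (vectorised).
#' @return F1 values.
#' @examples
#' f1(0.7, 0.78)   # 0.74 to two decimals
#' @export
f1 <- function(P, R) {
  if (any(P < 0 | P > 1 | R < 0 | R > 1, na.rm = TRUE))
    stop("precision and recall must lie in [0, 1]")
  ifelse(P + R == 0, 0, 2 * P * R / (P + R))
}

# assemble a tm_eval report from per-type TP and set sizes
make_eval_report <- function(types, tp, n_pred, n_gold, mode) {
  P <- ifelse(n_pred == 0, 0, tp / n_pred)
  R <- ifelse(n_gold == 0, 0, tp / n_gold)
  per_type <- data.frame(type = types, P = P, R = R, F = f1(P, R),
                         support = n_gold, stringsAsFactors = FALSE)
  per_type <- per_type[order(per_type$type), , drop = FALSE]
  rownames(per_type) <- NULL
  macro <- c(P = mean(per_type$P), R = mean(per_type$R), F = mean(per_type$F))
  w <- per_type$support
  weighted <- if (sum(w) == 0) c(P = 0, R = 0, F = 0) else
    c(P = sum(per_type$P * w) / sum(w), R = sum(per_type$R * w) / sum(w),
      F = sum(per_type$F * w) / sum(w))
  structure(list(per_type = per_type, macro = macro, weighted = weighted,
                 mode = mode),
            class = "tm_eval")
}

#' @export
print.tm_eval <- function(x, digits = 2L, ...) {
  cat(sprintf("<tm_eval mode=%s>\n", x$mode))
  pt <- x$per_type
  pt[c("P", "R", "F")] <- lapply(pt[c("P", "R", "F")], round, digits)
  print(pt, row.names = FALSE)
  cat(sprintf("macro:    P %.2f / R %.2f / F %.2f\n",
              x$macro["P"], x$macro["R"], x$macro["F"]))
  cat(sprintf("weighted: P %.2f / R %.2f / F %.2f\n",
              x$weighted["P"], x$weighted["R"], x$weighted["F"]))
  invisible(x)
}

# one-to-one multiset true positives between two key vectors
multiset_tp <- function(gold_keys, pred_keys) {
  gt <- table(gold_keys); pt <- table(pred_keys)
  common <- intersect(names(gt), names(pt))
  sum(pmin(as.integer(gt[common]), as.integer(pt[common])))
}

#' Strict entity evaluation
#'
#' A prediction is a true positive iff its character span and entity type
#' both match a gold annotation exactly (one-to-one within each document).
#'
#' @param gold,pred Entity tables with a `doc_id` column (see
#'   [corpus_entities()]), or lists of `tm_document`s.
#' @return A `tm_eval` report (per-type and macro/weighted P, R, F).
#' @export
strict_entity_eval <- function(gold, pred) {
  if (is.list(gold) && !is.data.frame(gold)) gold <- corpus_entities(gold)
  if (is.list(pred) && !is.data.frame(pred)) pred <- corpus_entities(pred)
  types <- sort(unique(c(gold$etype, pred$etype)))
  if (!length(types)) return(make_eval_report(character(0), numeric(0),
                                              numeric(0), numeric(0), "strict"))
  key <- function(e) paste(e$doc_id, e$start, e$end)
  tp <- vapply(types, function(tt)
    multiset_tp(key(gold[gold$etype == tt, ]), key(pred[pred$etype == tt, ])), 0)
  make_eval_report(types,
                   tp,
                   vapply(types, function(tt) sum(pred$etype == tt), 0),
                   vapply(types, function(tt) sum(gold$etype == tt), 0),
                   "strict")
}

#' CoNLL-style chunk evaluation of IOB2 sequences
#'
#' Chunks are extracted from the label sequences with lenient
#' (conlleval-compatible) repair -- an orphan `I-X` opens a chunk -- and a
#' predicted chunk counts iff its token range and type match a gold chunk
#' exactly. Gold and predicted sequences must share the tokenisation.
#'
#' @param gold,pred `tm_iob` objects or lists of them (parallel).
#' @return A `tm_eval` report.
#' @export
conll_entity_eval <- function(gold, pred) {
  if (inherits(gold, "tm_iob")) gold <- list(gold)
  if (inherits(pred, "tm_iob")) pred <- list(pred)
  stopifnot(length(gold) == length(pred))
  gold_ch <- list(); pred_ch <- list()
  for (i in seq_along(gold)) {
    g <- gold[[i]]; p <- pred[[i]]
    if (nrow(g$tokens) != nrow(p$tokens) ||
        any(g$tokens$token != p$tokens$token))
      stop(sprintf("tokenisation mismatch between gold and pred sequence %d", i))
    gc <- iob_chunks(g$labels, g$tokens$sentence)
    pc <- iob_chunks(p$labels, p$tokens$sentence)
    if (nrow(gc)) { gc$doc <- i; gold_ch[[length(gold_ch) + 1L]] <- gc }
    if (nrow(pc)) { pc$doc <- i; pred_ch[[length(pred_ch) + 1L]] <- pc }
  }
  gch <- if (length(gold_ch)) do.call(rbind, gold_ch) else
    data.frame(type = character(0), first = integer(0), last = integer(0),
               doc = integer(0))
  pch <- if (length(pred_ch)) do.call(rbind, pred_ch) else
    data.frame(type = character(0), first = integer(0), last = integer(0),
               doc = integer(0))
  types <- sort(unique(c(gch$type, pch$type)))
  if (!length(types)) return(make_eval_report(character(0), numeric(0),
                                              numeric(0), numeric(0), "conll"))
  key <- function(ch) paste(ch$doc, ch$first, ch$last)
  tp <- vapply(types, function(tt)
    multiset_tp(key(gch[gch$type == tt, ]), key(pch[pch$type == tt, ])), 0)
  make_eval_report(types,
                   tp,
                   vapply(types, function(tt) sum(pch$type == tt), 0),
                   vapply(types, function(tt) sum(gch$type == tt), 0),
                   "conll")
}

#' Relation evaluation
#'
#' A predicted relation is correct iff head span, tail span and relation
#' type all match a gold relation (one-to-one within each document).
#'
#' @param gold,pred Resolved relation tables (see [resolve_relations()] /
#'   [corpus_relations()]), or lists of `tm_document`s whose own relation
#'   layers are compared.
#' @return A `tm_eval` report keyed by relation type.
#' @export
relation_eval <- function(gold, pred) {
  if (is.list(gold) && !is.data.frame(gold)) gold <- corpus_relations(gold)
  if (is.list(pred) && !is.data.frame(pred)) pred <- corpus_relations(pred)
  types <- sort(unique(c(gold$rtype, pred$rtype)))
  if (!length(types)) return(make_eval_report(character(0), numeric(0),
                                              numeric(0), numeric(0), "relation"))
  key <- function(r) paste(r$doc_id, r$head_start, r$head_end,
                           r$tail_start, r$tail_end)
  tp <- vapply(types, function(tt)
    multiset_tp(key(gold[gold$rtype == tt, ]), key(pred[pred$rtype == tt, ])), 0)
  make_eval_report(types,
                   tp,
                   vapply(types, function(tt) sum(pred$rtype == tt), 0),
                   vapply(types, function(tt) sum(gold$rtype == tt), 0),
                   "relation")
}
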