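# Inter-annotator agreement: greedy tolerance-based span alignment between
# two annotators' layers and Cohen's kappa over the resulting units. Units
# are alignment products -- matched pairs categorised by both labels,
# unmatched annotations categorised against "none" -- with no synthetic
# true-negative mass, so kappa values depend on this unitisation (stated in
# the package vignette).

#' Align two annotators' entity spans
#'
#' Greedy one-to-one matching by increasing combined boundary distance
#' (`|start_a - start_b| + |end_a - end_b|`), ties broken by earlier start
#' then input order. `exact` mode admits identical spans only; `partial`
#' mode admits pairs with both boundary shifts within `tolerance`
#' characters.
#'
#' @param a,b Entity tables from the two annotators (same document).
#' @param mode `"exact"` or `"partial"`.
#' @param tolerance Per-boundary character tolerance for partial matches
#'   (default 4).
#' @return List of class `tm_alignment`: `pairs` (data frame `a_idx`,
#'   `b_idx`, `kind`, `dist`), `unmatched_a`, `unmatched_b` (row indices).
#' @export
align_spans <- function(a, b, mode = c("partial", "exact"), tolerance = 4L) {
  mode <- match.arg(mode)
  na <- nrow(a); nb <- nrow(b)
  cand <- expand.grid(a_idx = seq_len(na), b_idx = seq_len(nb))
  if (nrow(cand)) {
    ds <- abs(a$start[cand$a_idx] - b$start[cand$b_idx])
    de <- abs(a$end[cand$a_idx] - b$end[cand$b_idx])
    ok <- if (mode == "exact") ds == 0L & de == 0L
          else ds <= tolerance & de <= tolerance
    cand <- cand[ok, , drop = FALSE]
    cand$dist <- (ds + de)[ok]
  } else cand$dist <- numeric(0)
  cand <- cand[order(cand$dist, a$start[cand$a_idx], cand$a_idx, cand$b_idx), ,
               drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- cand[0, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    ai <- cand$a_idx[i]; bi <- cand$b_idx[i]
    if (used_a[ai] || used_b[bi]) next
    used_a[ai] <- TRUE; used_b[bi] <- TRUE
    pairs <- rbind(pairs, cand[i, , drop = FALSE])
  }
  pairs$kind <- ifelse(pairs$dist == 0, "exact", "partial")
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = which(!used_a),
                 unmatched_b = which(!used_b)),
            class = "tm_alignment")
}

# Cohen's kappa from paired category labels
kappa_from_units <- function(lab_a, lab_b) {
  n <- length(lab_a)
  if (n < 2L) stop("fewer than 2 agreement units: kappa undefined")
  cats <- union(lab_a, lab_b)
  tab <- table(factor(lab_a, cats), factor(lab_b, cats))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    if (p_o >= 1) 1 else 0  # degenerate single-category table
  } else (p_o - p_e) / (1 - p_e)
  list(kappa = kappa, p_o = p_o, p_e = p_e, table = tab)
}

#' Cohen's kappa for two annotators' entity layers
#'
#' Units are the alignment products of [align_spans()]: each matched pair is
#' one unit categorised `(a-type, b-type)`; each unmatched annotation is one
#' unit with `"none"` for the missing partner. Kappa is computed from the
#' resulting contingency table.
#'
#' @param a,b Entity tables from the two annotators.
#' @param mode `"partial"` (default) or `"exact"` span matching.
#' @param tolerance Per-boundary tolerance in characters (default 4).
#' @param doc_id Optional id recorded in the report.
#' @return List of class `tm_agreement`: `kappa`, `p_o`, `p_e`, `layer`,
#'   `mode`, `tolerance`, `unit_counts` (agreed / disagreed / unmatched_a /
#'   unmatched_b) and the contingency `table`.
#' @export
entity_kappa <- function(a, b, mode = c("partial", "exact"), tolerance = 4L,
                         doc_id = NA_character_) {
  mode <- match.arg(mode)
  al <- align_spans(a, b, mode = mode, tolerance = tolerance)
  lab_a <- c(a$etype[al$pairs$a_idx], a$etype[al$unmatched_a],
             rep("none", length(al$unmatched_b)))
  lab_b <- c(b$etype[al$pairs$b_idx], rep("none", length(al$unmatched_a)),
             b$etype[al$unmatched_b])
  k <- kappa_from_units(lab_a, lab_b)
  structure(list(doc_id = doc_id, layer = "entities", mode = mode,
                 tolerance = tolerance, kappa = k$kappa, p_o = k$p_o,
                 p_e = k$p_e,
                 unit_counts = c(agreed = sum(lab_a == lab_b),
                                 disagreed = sum(lab_a != lab_b &
                                                   lab_a != "none" &
                                                   lab_b != "none"),
                                 unmatched_a = length(al$unmatched_a),
                                 unmatched_b = length(al$unmatched_b)),
                 table = k$table),
            class = "tm_agreement")
}

#' Cohen's kappa for two annotators' relation layers
#'
#' Two relations match iff their types are equal and both endpoint spans
#' agree within the character tolerance. Matched pairs and unmatched
#' relations form the units ("none" for a missing partner) and kappa is
#' computed over them.
#'
#' @param a,b Resolved relation tables (see [resolve_relations()]) from the
#'   two annotators.
#' @param tolerance Per-boundary tolerance in characters (default 4).
#' @param doc_id Optional id recorded in the report.
#' @return A `tm_agreement` report (`layer = "relations"`).
#' @export
relation_agreement <- function(a, b, tolerance = 4L, doc_id = NA_character_) {
  na <- nrow(a); nb <- nrow(b)
  cand <- expand.grid(a_idx = seq_len(na), b_idx = seq_len(nb))
  if (nrow(cand)) {
    d <- abs(a$head_start[cand$a_idx] - b$head_start[cand$b_idx]) +
      abs(a$head_end[cand$a_idx] - b$head_end[cand$b_idx]) +
      abs(a$tail_start[cand$a_idx] - b$tail_start[cand$b_idx]) +
      abs(a$tail_end[cand$a_idx] - b$tail_end[cand$b_idx])
    ok <- a$rtype[cand$a_idx] == b$rtype[cand$b_idx] &
      abs(a$head_start[cand$a_idx] - b$head_start[cand$b_idx]) <= tolerance &
      abs(a$head_end[cand$a_idx] - b$head_end[cand$b_idx]) <= tolerance &
      abs(a$tail_start[cand$a_idx] - b$tail_start[cand$b_idx]) <= tolerance &
      abs(a$tail_end[cand$a_idx] - b$tail_end[cand$b_idx]) <= tolerance
    cand <- cand[ok, , drop = FALSE]; cand$dist <- d[ok]
  } else cand$dist <- numeric(0)
  cand <- cand[order(cand$dist, cand$a_idx, cand$b_idx), , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  pair_a <- integer(0); pair_b <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ai <- cand$a_idx[i]; bi <- cand$b_idx[i]
    if (used_a[ai] || used_b[bi]) next
    used_a[ai] <- TRUE; used_b[bi] <- TRUE
    pair_a <- c(pair_a, ai); pair_b <- c(pair_b, bi)
  }
  lab_a <- c(a$rtype[pair_a], a$rtype[!used_a], rep("none", sum(!used_b)))
  lab_b <- c(b$rtype[pair_b], rep("none", sum(!used_a)), b$rtype[!used_b])
  k <- kappa_from_units(lab_a, lab_b)
  structure(list(doc_id = doc_id, layer = "relations", mode = "partial",
                 tolerance = tolerance, kappa = k$kappa, p_o = k$p_o,
                 p_e = k$p_e,
                 unit_counts = c(agreed = sum(lab_a == lab_b),
                                 disagreed = 0L,
                                 unmatched_a = sum(!used_a),
                                 unmatched_b = sum(!used_b)),
                 table = k$table),
            class = "tm_agreement")
}

#' @export
print.tm_agreement <- function(x, ...) {
  cat(sprintf(
    "<tm_agreement %s/%s tol=%d%s> kappa = %.3f (p_o = %.3f, p_e = %.3f)\n",
    x$layer, x$mode, x$tolerance,
    if (is.na(x$doc_id)) "" else paste0(" doc=", x$doc_id),
    x$kappa, x$p_o, x$p_e))
  invisible(x)
}
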