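# Corpus and annotation statistics: per-document annotation densities per
# 1,000 characters and corpus-level summary tables with split bookkeeping.

#' Per-document annotation densities
#'
#' Density is `1000 * count / length_chars` for each entity type and
#' relation type present in the schema.
#'
#' @param doc A `tm_document` with positive length.
#' @return One-row data frame: `doc_id`, `length_chars`, one density column
#'   per entity type (`arthropod`, `trait`, `value`, `qualifier`) and per
#'   relation type (`hasTrait`, `hasValue`, `hasQualifier`).
#' @export
annotation_density <- function(doc) {
  if (doc$length == 0L) stop("zero-length document: density undefined")
  dens <- function(n) 1000 * n / doc$length
  etypes <- setdiff(ENTITY_TYPES, character(0))
  rtypes <- setdiff(RELATION_TYPES, "none")
  out <- data.frame(doc_id = doc$doc_id, length_chars = doc$length,
                    stringsAsFactors = FALSE)
  for (tt in etypes) out[[tt]] <- dens(sum(doc$entities$etype == tt))
  for (tt in rtypes) out[[tt]] <- dens(sum(doc$relations$rtype == tt))
  out
}

#' Corpus summary table
#'
#' Per-type entity and relation totals, the document-length median and
#' quartiles (linear-interpolation quantiles), per-split annotation totals
#' and the train/test annotation percentage, defined as
#' `100 * train / test` over combined entity + relation counts.
#'
#' @param docs List of `tm_document`s.
#' @return List of class `tm_corpus_summary` with `n_docs`,
#'   `entity_totals`, `relation_totals`, `length_stats`, `split_totals`,
#'   `train_test_percent`.
#' @export
corpus_summary <- function(docs) {
  etotals <- stats::setNames(integer(length(ENTITY_TYPES)), ENTITY_TYPES)
  rtotals <- stats::setNames(integer(length(RELATION_TYPES)), RELATION_TYPES)
  lens <- integer(0)
  split_tot <- c(`TRAIN-GOLD` = 0L, `TEST-GOLD` = 0L)
  for (d in docs) {
    for (tt in ENTITY_TYPES) etotals[tt] <- etotals[tt] + sum(d$entities$etype == tt)
    for (tt in RELATION_TYPES) rtotals[tt] <- rtotals[tt] + sum(d$relations$rtype == tt)
    lens <- c(lens, d$length)
    if (!is.na(d$split_tag))
      split_tot[d$split_tag] <- split_tot[d$split_tag] +
        nrow(d$entities) + nrow(d$relations)
  }
  q <- if (length(lens)) stats::quantile(lens, c(0.25, 0.5, 0.75), type = 7)
       else c(`25%` = NA_real_, `50%` = NA_real_, `75%` = NA_real_)
  ratio <- if (split_tot["TEST-GOLD"] > 0)
    round(100 * split_tot[["TRAIN-GOLD"]] / split_tot[["TEST-GOLD"]], 1L)
  else NA_real_
  structure(list(n_docs = length(docs),
                 entity_totals = etotals,
                 entity_total = sum(etotals),
                 relation_totals = rtotals,
                 relation_total = sum(rtotals),
                 length_stats = q,
                 split_totals = split_tot,
                 train_test_percent = ratio),
            class = "tm_corpus_summary")
}

#' @export
print.tm_corpus_summary <- function(x, ...) {
  cat(sprintf("<tm_corpus_summary> %d documents\n", x$n_docs))
  cat("entities: ", paste(names(x$entity_totals), x$entity_totals,
                          sep = " = ", collapse = ", "),
      sprintf(" (total %d)\n", x$entity_total))
  cat("relations:", paste(names(x$relation_totals), x$relation_totals,
                          sep = " = ", collapse = ", "),
      sprintf(" (total %d)\n", x$relation_total))
  if (!is.na(x$length_stats[2]))
    cat(sprintf("length: median %.0f chars (IQR %.0f-%.0f)\n",
                x$length_stats[2], x$length_stats[1], x$length_stats[3]))
  if (!is.na(x$train_test_percent))
    cat(sprintf("split: TRAIN-GOLD %d / TEST-GOLD %d annotations (%.1f%%)\n",
                x$split_totals[1], x$split_totals[2], x$train_test_percent))
  invisible(x)
}
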