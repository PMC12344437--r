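# Seeded generator of treatment-like synthetic corpora with planted gold
# entity and relation layers at exact character offsets, plus the matching
# toy taxon/trait dictionaries. Documents are assembled from sentence
# templates (species introductions, trait descriptions with colour or
# measurement values, measurement series, qualifier mentions, fillers)
# chosen deficit-first so realised per-type densities track the configured
# targets.

SIM_GENERA <- c("Tipula", "Nephrotoma", "Dolichopeza", "Ctenophora",
                "Pedicia", "Dicranota", "Limonia", "Erioptera")
SIM_EPITHETS <- c("oleracea", "maxima", "paludosa", "flavescens", "dorsalis",
                  "lunata", "cornicina", "vittata")
SIM_TRAITS <- list(
  # term, category, synonym (may be NA)
  c("femur", "morphology", "hind femur"),
  c("tibia", "morphology", NA),
  c("antenna", "morphology", NA),
  c("wing", "morphology", NA),
  c("mesonotum", "morphology", NA),
  c("rostrum", "morphology", NA),
  c("tergite", "morphology", NA),
  c("scutellum", "morphology", NA),
  c("wetland", "habitat", NA),
  c("leaf litter", "habitat", NA),
  c("rotting wood", "habitat", NA),
  c("nectarivorous", "feeding ecology", NA),
  c("predatory", "feeding ecology", NA),
  c("saprophagous", "feeding ecology", NA)
)
SIM_COLORS <- c("yellow", "brown", "black", "silvery", "brownish-yellow",
                "greyish-brown")
SIM_FILLERS <- c(
  "Specimens were examined under magnification.",
  "Additional material was studied in detail.",
  "The distribution remains poorly documented.",
  "Further records are expected from nearby localities.",
  "Comparative notes follow the standard terminology.",
  "Type material is deposited in the reference collection."
)

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the manually annotated treatment corpus: per-1,000
#' character densities of 4.9 arthropod, 6.4 trait and 6.1 value mentions
#' (the gold-set medians), all traits linked to an arthropod mention where
#' one occurs within the six-sentence window (few-to-many `hasTrait`), all
#' values linked one-to-one to a same-sentence trait (`hasValue`), and no
#' noise.
#'
#' @param seed Integer seed; generation is deterministic given it.
#' @param n_docs Number of documents (default 25, the gold-set size).
#' @param doc_length_range Target document lengths in characters.
#' @param density_arthropod,density_trait,density_value,density_qualifier
#'   Target planted mentions per 1,000 characters.
#' @param p_trait_linked Probability a planted trait is linked to the
#'   nearest preceding in-window arthropod mention.
#' @param p_value_linked Probability a planted value comes with a
#'   same-sentence trait it links to (otherwise a bare measurement series is
#'   planted).
#' @param synonym_variant_rate Probability a trait mention uses a synonym
#'   surface instead of the preferred term.
#' @param plural_rate Probability a trait mention is pluralised.
#' @param unknown_taxon_rate Probability an arthropod mention uses a surface
#'   absent from the toy dictionary.
#' @return List of class `tm_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_docs = 25L,
                       doc_length_range = c(2000L, 4000L),
                       density_arthropod = 4.9, density_trait = 6.4,
                       density_value = 6.1, density_qualifier = 0.8,
                       p_trait_linked = 1.0, p_value_linked = 1.0,
                       synonym_variant_rate = 0.0, plural_rate = 0.0,
                       unknown_taxon_rate = 0.0) {
  cfg <- list(seed = as.integer(seed), n_docs = as.integer(n_docs),
              doc_length_range = as.integer(doc_length_range),
              density_arthropod = density_arthropod,
              density_trait = density_trait, density_value = density_value,
              density_qualifier = density_qualifier,
              p_trait_linked = p_trait_linked,
              p_value_linked = p_value_linked,
              synonym_variant_rate = synonym_variant_rate,
              plural_rate = plural_rate,
              unknown_taxon_rate = unknown_taxon_rate)
  dens <- c(cfg$density_arthropod, cfg$density_trait, cfg$density_value,
            cfg$density_qualifier)
  rates <- c(cfg$p_trait_linked, cfg$p_value_linked, cfg$synonym_variant_rate,
             cfg$plural_rate, cfg$unknown_taxon_rate)
  if (any(dens < 0)) stop("densities must be >= 0")
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  # each planted mention costs roughly 30-45 characters of sentence; much
  # higher total densities than ~22/1,000 cannot be realised
  if (sum(dens) > 22) stop("infeasible config: total density too high for treatment-like sentences")
  structure(cfg, class = "tm_sim_config")
}

#' Build the toy dictionaries the generator plants from
#'
#' @param expand_plurals Add regular plural variants to the trait
#'   dictionary (matches what the tagger expects).
#' @return List with `taxon` and `trait` `tm_dictionary` objects.
#' @export
sim_dictionaries <- function(expand_plurals = TRUE) {
  binomials <- as.vector(outer(SIM_GENERA, SIM_EPITHETS, paste))
  taxa <- data.frame(
    concept_id = c(sprintf("TX:G%02d", seq_along(SIM_GENERA)),
                   sprintf("TX:S%03d", seq_along(binomials))),
    preferred_term = c(SIM_GENERA, binomials),
    kind = "taxon",
    category = c(rep("genus", length(SIM_GENERA)),
                 rep("species", length(binomials))),
    trait_type = NA_character_, source_uri = NA_character_,
    lineage = NA_character_, stringsAsFactors = FALSE)
  taxa$synonyms <- replicate(nrow(taxa), character(0), simplify = FALSE)
  traits <- data.frame(
    concept_id = sprintf("TR:%03d", seq_along(SIM_TRAITS)),
    preferred_term = vapply(SIM_TRAITS, `[`, "", 1L),
    kind = "trait",
    category = vapply(SIM_TRAITS, `[`, "", 2L),
    trait_type = NA_character_, source_uri = NA_character_,
    lineage = NA_character_, stringsAsFactors = FALSE)
  traits$synonyms <- lapply(SIM_TRAITS, function(x)
    if (is.na(x[3])) character(0) else x[3])
  trait_dict <- new_dictionary(traits)
  if (expand_plurals) trait_dict <- expand_plural_variants(trait_dict)
  list(taxon = new_dictionary(taxa), trait = trait_dict)
}

#' Generate a synthetic treatment-like corpus with planted gold layers
#'
#' Documents are concatenations of template sentences; every planted entity
#' is recorded at its exact character span and every planted relation in the
#' gold relation layer. With all noise rates at zero, every planted surface
#' is a dictionary form (or value-pattern/qualifier-lexicon form) and the
#' planted relations follow the nearest-mention rules, so the baseline
#' taggers and the proximity predictor recover the gold layers exactly.
#'
#' @param cfg A `tm_sim_config`.
#' @return List of class `tm_sim_corpus`: `documents` (list of
#'   `tm_document`), `taxon_dict`, `trait_dict`, `config`.
#' @export
generate_corpus <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "tm_sim_config"))
  dicts <- sim_dictionaries()
  docs <- local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_docs), function(i)
      generate_document(sprintf("sim_%03d", i), cfg))
  })
  structure(list(documents = docs, taxon_dict = dicts$taxon,
                 trait_dict = dicts$trait, config = cfg),
            class = "tm_sim_corpus")
}

# one document; relies on the caller having seeded the RNG
generate_document <- function(doc_id, cfg) {
  L <- if (cfg$doc_length_range[1] == cfg$doc_length_range[2])
    cfg$doc_length_range[1]
  else sample(cfg$doc_length_range[1]:cfg$doc_length_range[2], 1L)
  need <- c(a = round(cfg$density_arthropod * L / 1000),
            t = round(cfg$density_trait * L / 1000),
            v = round(cfg$density_value * L / 1000),
            q = round(cfg$density_qualifier * L / 1000))
  binomials <- as.vector(outer(SIM_GENERA, SIM_EPITHETS, paste))
  trait_terms <- vapply(SIM_TRAITS, `[`, "", 1L)
  trait_syns <- vapply(SIM_TRAITS, `[`, "", 3L)

  text <- ""
  ents <- list()     # rows: start, end, etype, sentence
  rels <- list()     # rows: head index, tail index (into ents), rtype
  sent_no <- 0L

  add_sentence <- function(sentence, local_entities) {
    # local_entities: list of c(start, end, etype) relative to the sentence
    base <- nchar(text)
    sep <- if (base > 0L) 1L else 0L
    text <<- if (base > 0L) paste0(text, " ", sentence) else sentence
    sent_no <<- sent_no + 1L
    idx <- integer(length(local_entities))
    for (j in seq_along(local_entities)) {
      le <- local_entities[[j]]
      ents[[length(ents) + 1L]] <<- data.frame(
        start = base + sep + as.integer(le[[1]]),
        end = base + sep + as.integer(le[[2]]),
        etype = le[[3]], sentence = sent_no, stringsAsFactors = FALSE)
      idx[j] <- length(ents)
    }
    idx
  }
  span_of <- function(sentence, surface) {
    s <- regexpr(surface, sentence, fixed = TRUE)
    c(as.integer(s) - 1L, as.integer(s) - 1L + nchar(surface))
  }
  last_arthropod_in_window <- function() {
    # nearest preceding arthropod mention within the 6-sentence bound
    ai <- which(vapply(ents, function(x) x$etype == "arthropod", TRUE))
    if (!length(ai)) return(NA_integer_)
    cand <- ai[vapply(ents[ai], function(x) sent_no - x$sentence < 6L, TRUE)]
    if (!length(cand)) return(NA_integer_)
    cand[length(cand)]
  }
  plant_trait_surface <- function() {
    k <- sample(seq_along(trait_terms), 1L)
    surf <- trait_terms[k]
    if (!is.na(trait_syns[k]) && stats::runif(1) < cfg$synonym_variant_rate)
      surf <- trait_syns[k]
    if (stats::runif(1) < cfg$plural_rate) {
      pl <- pluralize(surf)
      if (!is.na(pl)) surf <- pl
    }
    surf
  }
  plant_taxon_surface <- function() {
    if (stats::runif(1) < cfg$unknown_taxon_rate)
      paste("Novogenus", sample(c("crypticus", "incognitus", "absconditus"), 1L))
    else sample(binomials, 1L)
  }

  while (any(need > 0)) {
    target <- names(need)[which.max(need)]
    if (target == "q") {
      if (need["a"] > 0) {
        taxon <- plant_taxon_surface()
        s <- paste0(taxon, " female differs markedly.")
        idx <- add_sentence(s, list(
          c(span_of(s, taxon), "arthropod"),
          c(span_of(s, "female"), "qualifier")))
        rels[[length(rels) + 1L]] <- data.frame(
          head = idx[1], tail = idx[2], rtype = "hasQualifier")
        need["a"] <- need["a"] - 1L
      } else {
        s <- "Notably the female paratype differs."
        add_sentence(s, list(c(span_of(s, "female"), "qualifier")))
      }
      need["q"] <- need["q"] - 1L
    } else if (target == "a") {
      taxon <- plant_taxon_surface()
      s <- paste0(taxon, " sp. nov. resembles its congeners.")
      add_sentence(s, list(c(span_of(s, taxon), "arthropod")))
      need["a"] <- need["a"] - 1L
    } else if (target == "t" ||
               (need["t"] > 0 && stats::runif(1) < cfg$p_value_linked)) {
      # trait sentence, with a linked value while value deficit remains
      trait <- plant_trait_surface()
      with_value <- need["v"] > 0
      if (with_value && stats::runif(1) < 0.5) {
        color <- sample(SIM_COLORS, 1L)
        s <- paste0("The ", trait, " is mostly ", color, ".")
        vspan <- span_of(s, color)
      } else if (with_value) {
        x <- sprintf("%.1f", stats::runif(1, 1, 60))
        s <- paste0("The ", trait, " measures ", x, " mm.")
        vspan <- span_of(s, paste0(x, " mm"))
      } else {
        s <- paste0("The ", trait, " appears strongly reduced.")
        vspan <- NULL
      }
      locs <- list(c(span_of(s, trait), "trait"))
      if (!is.null(vspan)) locs <- c(locs, list(c(vspan, "value")))
      idx <- add_sentence(s, locs)
      if (!is.null(vspan)) {
        rels[[length(rels) + 1L]] <- data.frame(
          head = idx[1], tail = idx[2], rtype = "hasValue")
        need["v"] <- need["v"] - 1L
      }
      head_a <- last_arthropod_in_window()
      if (!is.na(head_a) && stats::runif(1) < cfg$p_trait_linked)
        rels[[length(rels) + 1L]] <- data.frame(
          head = head_a, tail = idx[1], rtype = "hasTrait")
      need["t"] <- need["t"] - 1L
    } else {
      # bare measurement series: an unlinked value
      xs <- paste(sample(10:99, sample(3:5, 1L)), collapse = ", ")
      s <- paste0("Segment ratios respectively ", xs, ".")
      add_sentence(s, list(c(span_of(s, xs), "value")))
      need["v"] <- need["v"] - 1L
    }
    if (nchar(text) > 3L * L)
      stop("infeasible config: densities too high for the document length")
  }
  while (nchar(text) < L)
    add_sentence(sample(SIM_FILLERS, 1L), list())

  entities <- if (length(ents)) do.call(rbind, ents) else
    data.frame(start = integer(0), end = integer(0), etype = character(0),
               sentence = integer(0))
  etab <- entity_table(entities$start, entities$end, entities$etype,
                       text = text)
  rtab <- if (length(rels)) {
    r <- do.call(rbind, rels)
    data.frame(head = etab$entity_id[r$head], tail = etab$entity_id[r$tail],
               rtype = r$rtype, stringsAsFactors = FALSE)
  } else empty_relations()
  tm_document(doc_id, text, etab, rtab)
}

#' Planted-truth report for a synthetic corpus
#'
#' Emits the planted per-type totals, per-document densities and relation
#' label counts of a corpus produced by [generate_corpus()], for use as the
#' oracle by downstream tests. Refuses corpora this generator did not
#' produce.
#'
#' @param corpus A `tm_sim_corpus`.
#' @return List with `entity_totals`, `relation_totals`, `densities` (one
#'   row per document, from [annotation_density()]) and `summary`
#'   ([corpus_summary()] of the gold layers).
#' @export
corpus_truth_report <- function(corpus) {
  if (!inherits(corpus, "tm_sim_corpus"))
    stop("corpus_truth_report() only accepts corpora from generate_corpus()")
  docs <- corpus$documents
  summ <- corpus_summary(docs)
  dens <- do.call(rbind, lapply(docs, annotation_density))
  list(entity_totals = summ$entity_totals,
       relation_totals = summ$relation_totals,
       densities = dens, summary = summ)
}

#' @export
print.tm_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<tm_sim_config> seed=%d, %d docs of %d-%d chars; ",
                     "densities A=%.1f T=%.1f V=%.1f Q=%.1f per 1,000\n"),
              x$seed, x$n_docs, x$doc_length_range[1], x$doc_length_range[2],
              x$density_arthropod, x$density_trait, x$density_value,
              x$density_qualifier))
  invisible(x)
}

#' Generate a synthetic trait-dictionary table
#'
#' A stand-in, built in code, shaped like the curated trait-dictionary
#' spreadsheet: columns `term`, `category`, `trait_type`, `synonyms`,
#' `source_uri`, with 390 rows -- 81 feeding ecology, 184 habitat and 125
#' morphology terms. The terms themselves are synthetic; the table exists
#' so the loader and its category accounting can be exercised offline.
#'
#' @return Data frame with 390 rows.
#' @export
synthetic_trait_table <- function() {
  counts <- c(`feeding ecology` = 81L, habitat = 184L, morphology = 125L)
  types <- c("yes/no", "association", "measurement", "length/width", "count")
  rows <- lapply(names(counts), function(cat) {
    n <- counts[[cat]]
    stem <- sub(" .*", "", cat)
    term <- sprintf("%s trait %03d", stem, seq_len(n))
    data.frame(term = term, category = cat,
               trait_type = rep_len(types, n),
               synonyms = ifelse(seq_len(n) %% 3L == 0L,
                                 paste0(term, " form; ", term, " state"), ""),
               source_uri = sprintf("http://example.org/%s/%03d",
                                    gsub(" ", "-", cat), seq_len(n)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
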