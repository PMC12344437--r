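# Pipeline wiring: run selected stages of the mining workflow in order over
# a corpus, write artifacts and a run log, and make reruns with the same
# configuration reproduce identical outputs.

PIPELINE_STAGES <- c("simulate", "tag", "normalize", "candidates", "predict",
                     "eval", "stats")

# small deterministic config fingerprint (polynomial rolling hash over the
# serialised object; stays within exact double-precision integers)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 999999937
  sprintf("%09.0f", h)
}

#' Run the mining workflow
#'
#' Executes the selected stages in their canonical order
#' (simulate -> tag -> normalize -> candidates -> predict -> eval -> stats)
#' over a synthetic corpus or a BioC collection, writing artifacts and a
#' plain-text run log to `out_dir`. Rerunning with an identical
#' configuration reproduces identical outputs (every artifact records the
#' configuration hash).
#'
#' @param config Named list (or path to a YAML file, read with \pkg{yaml})
#'   with elements: `stages` (subset of the stage names), `out_dir`,
#'   `seed`, and either `input_bioc` (path) or `sim` (arguments passed to
#'   [sim_config()]); optional `max_sentences`, `flank`.
#' @return Invisibly, a list with the in-memory stage outputs and the run
#'   log path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop(sprintf("unknown stage name '%s'", unknown[1]))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  max_sentences <- as.integer(config$max_sentences %||% 6L)
  hash <- config_hash(config[order(names(config))])
  log_path <- file.path(out_dir, "run_log.txt")
  log_con <- file(log_path, "w"); on.exit(close(log_con))
  logline <- function(...) writeLines(sprintf(...), log_con)
  logline("traitmine pipeline run")
  logline("package version: %s", as.character(utils::packageVersion("traitmine")))
  logline("config hash: %s", hash)
  logline("seed: %d", seed)
  logline("stages: %s", paste(stages, collapse = ", "))

  state <- list(config_hash = hash)
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    state <- switch(stage,
      simulate = {
        cfg <- do.call(sim_config, c(list(seed = seed), config$sim))
        corpus <- generate_corpus(cfg)
        write_bioc_collection(corpus$documents,
                              file.path(out_dir, "corpus_gold.bioc.json"))
        c(state, list(gold = corpus$documents, taxon_dict = corpus$taxon_dict,
                      trait_dict = corpus$trait_dict))
      },
      tag = {
        docs <- state$gold %||% read_bioc_collection(config$input_bioc)
        if (is.null(state$gold)) state$gold <- docs
        tagged <- lapply(docs, tag_document,
                         taxon_dict = state$taxon_dict,
                         trait_dict = state$trait_dict)
        write_bioc_collection(tagged,
                              file.path(out_dir, "corpus_tagged.bioc.json"))
        c(state, list(tagged = tagged))
      },
      normalize = {
        if (is.null(state$tagged)) stop("dependency error: stage 'normalize' needs 'tag'")
        normed <- lapply(state$tagged, normalize_document,
                         taxon_dict = state$taxon_dict,
                         trait_dict = state$trait_dict)
        ents <- corpus_entities(normed)
        rep <- list(
          taxa = unclass(summarize_normalization(ents, "arthropod")),
          traits = unclass(summarize_normalization(ents, "trait",
                                                   dict = state$trait_dict)))
        jsonlite::write_json(rep, file.path(out_dir, "normalization.json"),
                             auto_unbox = TRUE, digits = NA)
        state$tagged <- normed
        state
      },
      candidates = {
        if (is.null(state$tagged)) stop("dependency error: stage 'candidates' needs 'tag'")
        cands <- do.call(rbind, lapply(state$tagged, generate_candidates,
                                       max_sentences = max_sentences))
        write_re_jsonl(cands, file.path(out_dir, "candidates.jsonl"))
        c(state, list(candidates = cands))
      },
      predict = {
        if (is.null(state$tagged)) stop("dependency error: stage 'predict' needs 'tag'")
        preds <- lapply(state$tagged, function(d) {
          d$relations <- predict_proximity_relations(d, max_sentences)
          d
        })
        write_bioc_collection(preds,
                              file.path(out_dir, "corpus_predicted.bioc.json"))
        state$tagged <- preds
        c(state, list(predicted = preds))
      },
      eval = {
        if (is.null(state$predicted) || is.null(state$gold))
          stop("dependency error: stage 'eval' needs 'predict' and gold annotations")
        ent_rep <- strict_entity_eval(state$gold, state$predicted)
        rel_rep <- relation_eval(state$gold, state$predicted)
        jsonlite::write_json(
          list(entities = ent_rep$per_type, entity_macro = ent_rep$macro,
               relations = rel_rep$per_type, relation_macro = rel_rep$macro),
          file.path(out_dir, "evaluation.json"), auto_unbox = TRUE,
          digits = NA)
        c(state, list(entity_eval = ent_rep, relation_eval = rel_rep))
      },
      stats = {
        docs <- state$gold %||% stop("dependency error: stage 'stats' needs a corpus")
        summ <- corpus_summary(docs)
        dens <- do.call(rbind, lapply(docs, annotation_density))
        utils::write.table(dens, file.path(out_dir, "densities.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        jsonlite::write_json(
          list(entity_totals = as.list(summ$entity_totals),
               relation_totals = as.list(summ$relation_totals)),
          file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
        c(state, list(summary = summ))
      }
    )
    logline("stage %-10s done in %.2fs", stage,
            proc.time()[["elapsed"]] - t0)
  }
  state$log_path <- log_path
  invisible(state)
}
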