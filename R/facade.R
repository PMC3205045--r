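TYPE_PRIORITY <- c(CM = 1, ONT = 2, CPR = 3, RN = 4, CJ = 5, ASE = 6,
                   DATA = 7)

fixture_path <- function(file) {
  system.file("extdata", file, package = "chemtext", mustWork = TRUE)
}

#' Default n-gram model trained on the packaged fixture word lists
#'
#' @param n,alpha,prior_chem Passed to \code{\link{ngram_train}}.
#' @return An \code{"ngram_model"}.
#' @export
default_ngram_model <- function(n = 4L, alpha = 1.0, prior_chem = 0.5) {
  lists <- build_word_lists(
    read_word_list(fixture_path("chemical_words.txt")),
    read_word_list(fixture_path("english_words.txt")))
  ngram_train(lists, n, alpha, prior_chem)
}

#' Construct a text-mining pipeline
#'
#' The single-object API: tokenisation, one active entity recogniser
#' (pattern, MEMM or regex), always-on lexicon stages (ontology lookup and
#' chemical-prefix detection), the experimental-data parser and a dictionary
#' registry for name-to-structure resolution. Zero-argument construction
#' loads the packaged fixture resources and "just works"; no files or
#' directories are ever created. Pipelines are plain immutable values: two
#' pipelines with different components coexist in one process and give
#' independent results.
#'
#' @param recogniser \code{"pattern"}, \code{"memm"} or \code{"regex"}.
#' @param tokeniser A \code{\link{tokeniser_config}}.
#' @param ngram_model An \code{\link{ngram_train}} model (default: trained
#'   on the packaged word lists).
#' @param memm_model A \code{\link{memm_train}} model (required when
#'   \code{recogniser = "memm"}).
#' @param patterns A \code{\link{pattern_config}}.
#' @param regex A \code{\link{regex_config}}.
#' @param ontology An \code{\link{ontology_terms}} table, or \code{NULL} to
#'   disable the stage.
#' @param prefix A \code{\link{prefix_automaton}}, or \code{NULL} to
#'   disable.
#' @param registry A \code{\link{dictionary_registry}}.
#' @param verbose Log stage counts via \code{message()}.
#' @return An object of class \code{"chem_pipeline"}.
#' @export
chem_pipeline <- function(recogniser = c("pattern", "memm", "regex"),
                          tokeniser = tokeniser_config(),
                          ngram_model = default_ngram_model(),
                          memm_model = NULL,
                          patterns = pattern_config(),
                          regex = regex_config(),
                          ontology = read_ontology_terms(
                            fixture_path("fixture_ontology.tsv")),
                          prefix = read_prefix_grammar(
                            fixture_path("prefix_grammar.json")),
                          registry = dictionary_registry(list(
                            read_chem_name_dict(
                              fixture_path("fixture_dictionary.tsv"),
                              "fixture"))),
                          verbose = FALSE) {
  recogniser <- match.arg(recogniser)
  p <- structure(list(recogniser = recogniser, tokeniser = tokeniser,
                      ngram_model = ngram_model, memm_model = NULL,
                      patterns = patterns, regex = regex,
                      ontology = ontology, prefix = prefix,
                      registry = registry, verbose = verbose),
                 class = "chem_pipeline")
  if (!is.null(memm_model)) p <- set_component(p, "memm_model", memm_model)
  p
}

#' @export
print.chem_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<pipeline: recogniser=%s, ontology=%s, prefix=%s, ",
                     "dictionaries=%d, memm=%s>\n"),
              x$recogniser,
              if (is.null(x$ontology)) "off" else "on",
              if (is.null(x$prefix)) "off" else "on",
              length(x$registry$dicts),
              if (is.null(x$memm_model)) "none" else "loaded"))
  invisible(x)
}

#' Replace a pipeline component
#'
#' Functional update: returns a new pipeline, never mutates shared state.
#' Setting a MEMM model whose feature-template version differs from the
#' package's raises a configuration error.
#'
#' @param pipeline A \code{\link{chem_pipeline}}.
#' @param component One of \code{"recogniser"}, \code{"tokeniser"},
#'   \code{"ngram_model"}, \code{"memm_model"}, \code{"patterns"},
#'   \code{"regex"}, \code{"ontology"}, \code{"prefix"}, \code{"registry"}.
#' @param value The replacement component.
#' @return The updated pipeline.
#' @export
set_component <- function(pipeline, component, value) {
  stopifnot(inherits(pipeline, "chem_pipeline"))
  component <- match.arg(component,
                         c("recogniser", "tokeniser", "ngram_model",
                           "memm_model", "patterns", "regex", "ontology",
                           "prefix", "registry"))
  check <- switch(component,
    recogniser = is.character(value) &&
      value %in% c("pattern", "memm", "regex"),
    tokeniser = inherits(value, "tokeniser_config"),
    ngram_model = inherits(value, "ngram_model"),
    memm_model = inherits(value, "memm_model"),
    patterns = inherits(value, "pattern_config"),
    regex = inherits(value, "regex_config"),
    ontology = is.null(value) || inherits(value, "ontology_terms"),
    prefix = is.null(value) || inherits(value, "prefix_automaton"),
    registry = inherits(value, "dictionary_registry"))
  if (!isTRUE(check))
    stop("configuration error: invalid value for component ", component)
  if (component == "memm_model" &&
      value$template_version != MEMM_TEMPLATE_VERSION)
    stop("configuration error: MEMM model was trained with feature ",
         "templates ", value$template_version, ", this build uses ",
         MEMM_TEMPLATE_VERSION)
  pipeline[[component]] <- value
  pipeline
}

entity_span_len <- function(e) e$end - e$start

#' Merge candidate entities from all recogniser stages
#'
#' Overlapping candidates are resolved by a deterministic cascade: the
#' longer span wins; on equal length, type priority CM > ONT > CPR > RN >
#' CJ > ASE; on equal priority, the higher confidence. Chemical-prefix
#' (CPR) entities that abut or lie inside a surviving CM span are dropped.
#' The result is sorted by start offset; merging an already-merged list is
#' the identity.
#'
#' @param entities List of candidate \code{\link{named_entity}} objects.
#' @return Merged, non-overlapping entity list.
#' @export
merge_entities <- function(entities) {
  if (!length(entities)) return(list())
  len <- vapply(entities, entity_span_len, integer(1))
  pri <- TYPE_PRIORITY[vapply(entities, `[[`, character(1), "type")]
  conf <- vapply(entities, `[[`, numeric(1), "confidence")
  conf[is.na(conf)] <- -1
  starts <- vapply(entities, `[[`, integer(1), "start")
  ord <- order(-len, pri, -conf, starts)
  accepted <- list()
  for (i in ord) {
    e <- entities[[i]]
    if (!any(vapply(accepted, entities_overlap, logical(1), b = e)))
      accepted[[length(accepted) + 1L]] <- e
  }
  cms <- Filter(function(e) e$type == "CM", accepted)
  accepted <- Filter(function(e) {
    if (e$type != "CPR") return(TRUE)
    !any(vapply(cms, function(cm)
      (e$start >= cm$start && e$end <= cm$end) ||
        e$end == cm$start || e$start == cm$end, logical(1)))
  }, accepted)
  accepted[order(vapply(accepted, `[[`, integer(1), "start"))]
}

pipeline_candidates <- function(pipeline, seq) {
  cand <- switch(pipeline$recogniser,
    pattern = pattern_find_entities(seq, pipeline$ngram_model,
                                    pipeline$patterns),
    regex = regex_find(seq, pipeline$regex),
    memm = {
      if (is.null(pipeline$memm_model))
        stop("configuration error: recogniser \"memm\" needs a model")
      memm_decode(seq, pipeline$memm_model, pipeline$ngram_model)
    })
  if (!is.null(pipeline$ontology))
    cand <- c(cand, ontology_find(seq, pipeline$ontology))
  if (!is.null(pipeline$prefix))
    cand <- c(cand, prefix_find(seq, pipeline$prefix))
  cand
}

#' Find named entities in plain text
#'
#' Tokenises the (NFC-normalised) text, runs the active recogniser plus the
#' lexicon stages on every paragraph, and merges the candidates under the
#' overlap policy of \code{\link{merge_entities}}. Offsets index the
#' normalised text, 0-based and half-open.
#'
#' @param pipeline A \code{\link{chem_pipeline}}.
#' @param text Document text.
#' @return List of \code{\link{named_entity}} objects sorted by start.
#' @export
findNamedEntities <- function(pipeline, text) {
  stopifnot(inherits(pipeline, "chem_pipeline"))
  if (!nzchar(text)) return(list())
  seqs <- tokenise_document(text, pipeline$tokeniser)
  out <- list()
  for (seq in seqs) {
    cand <- pipeline_candidates(pipeline, seq)
    merged <- merge_entities(cand)
    if (pipeline$verbose)
      message(sprintf("paragraph at %d: %d candidates -> %d entities",
                      seq$offset, length(cand), length(merged)))
    out <- c(out, merged)
  }
  out
}

#' Find named entities and resolve chemicals to structures
#'
#' Runs \code{\link{findNamedEntities}}, then resolves every CM entity
#' through the dictionary registry. Spans are never altered by resolution.
#'
#' @inheritParams findNamedEntities
#' @return List with components \code{resolved} (list of
#'   \code{\link{resolved_named_entity}}) and \code{unresolved} (entities
#'   without structures), both in document order.
#' @export
findAndResolveNamedEntities <- function(pipeline, text) {
  entities <- findNamedEntities(pipeline, text)
  resolved <- list(); unresolved <- list()
  for (e in entities) {
    r <- if (e$type == "CM") resolve_entity(e, pipeline$registry) else NULL
    if (is.null(r)) unresolved[[length(unresolved) + 1L]] <- e
    else resolved[[length(resolved) + 1L]] <- r
  }
  list(resolved = resolved, unresolved = unresolved)
}

#' Find only entities resolvable to chemical structures
#'
#' Exactly the \code{resolved} subset of
#' \code{\link{findAndResolveNamedEntities}}: entities such as "benzene"
#' that the registry can map to at least one structure, omitting spans like
#' "the methyl ester" that it cannot.
#'
#' @inheritParams findNamedEntities
#' @return List of \code{\link{resolved_named_entity}} objects.
#' @export
findResolvableEntities <- function(pipeline, text) {
  findAndResolveNamedEntities(pipeline, text)$resolved
}

#' Locate experimental data in text
#'
#' Pipeline wrapper around \code{\link{find_data}}.
#'
#' @inheritParams findNamedEntities
#' @return List of \code{"chem_data_annotation"} objects.
#' @export
findData <- function(pipeline, text) {
  stopifnot(inherits(pipeline, "chem_pipeline"))
  find_data(text)
}

#' Convert data annotations to DATA-typed entities
#'
#' Lets experimental-data spans share the standoff channel with named
#' entities.
#'
#' @param anns List of \code{"chem_data_annotation"} objects.
#' @return List of \code{\link{named_entity}} objects of type DATA.
#' @export
data_annotation_entities <- function(anns) {
  lapply(anns, function(a)
    named_entity(a$surface, "DATA", a$start, a$end))
}
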