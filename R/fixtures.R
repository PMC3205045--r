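# Run code under a temporary RNG state so generators are reproducible
# without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

CLASS_SUFFIXES <- list(CM = c("ol", "ane", "ate"),
                       RN = c("ation", "olysis"),
                       CJ = c("ic", "ous"),
                       ASE = c("ase"))

SYLLABLES <- c("meth", "eth", "prop", "but", "pent", "hex", "hept", "oct",
               "benz", "phen", "chlor", "brom", "fluor", "iod", "oxy",
               "hydr", "cycl", "amin", "nitr", "sulf", "carb", "vin",
               "tol", "xyl", "naphth", "pyr", "fur", "thi", "azo", "keto")

#' Specification for the synthetic corpus generator
#'
#' Defines the study conditions for training and evaluating the sequence
#' tagger without real annotated text: sentence count, vocabulary sizes, the
#' suffix rule that makes a token chemical, the rate at which entity tokens
#' are inserted, the multi-token entity rate, the class mix and a mandatory
#' seed.
#'
#' @param n_sentences Number of sentences (one document each).
#' @param n_chemical Chemical vocabulary size.
#' @param n_plain Plain vocabulary size (capped at the packaged list).
#' @param suffixes Chemical (CM) suffix rule.
#' @param entity_rate Probability an inserted slot carries an entity.
#' @param multi_rate Probability an entity spans two tokens.
#' @param class_mix Named probabilities over CM/RN/CJ/ASE.
#' @param seed Mandatory RNG seed.
#' @return An object of class \code{"corpus_spec"}.
#' @export
corpus_spec <- function(n_sentences = 500L, n_chemical = 120L,
                        n_plain = 200L, suffixes = CLASS_SUFFIXES$CM,
                        entity_rate = 0.25, multi_rate = 0.2,
                        class_mix = c(CM = 0.7, RN = 0.1, CJ = 0.1,
                                      ASE = 0.1),
                        seed = 1L) {
  stopifnot(entity_rate >= 0, entity_rate <= 1, multi_rate >= 0,
            multi_rate <= 1, !is.null(seed),
            setequal(names(class_mix), names(CLASS_SUFFIXES)),
            abs(sum(class_mix) - 1) < 1e-8)
  structure(list(n_sentences = as.integer(n_sentences),
                 n_chemical = as.integer(n_chemical),
                 n_plain = as.integer(n_plain), suffixes = suffixes,
                 entity_rate = entity_rate, multi_rate = multi_rate,
                 class_mix = class_mix, seed = as.integer(seed)),
            class = "corpus_spec")
}

random_words <- function(k, suffixes) {
  n_syl <- sample(1:3, k, replace = TRUE)
  vapply(seq_len(k), function(i)
    paste0(paste(sample(SYLLABLES, n_syl[i], replace = TRUE),
                 collapse = ""),
           sample(suffixes, 1)),
    character(1))
}

plain_vocabulary <- function(n_plain) {
  words <- read_word_list(system.file("extdata", "english_words.txt",
                                      package = "chemtext",
                                      mustWork = TRUE))
  # plain words must not satisfy any entity suffix rule
  all_suf <- unlist(CLASS_SUFFIXES)
  ok <- !vapply(words, function(w)
    any(endsWith(w, all_suf)), logical(1), USE.NAMES = FALSE)
  utils::head(words[ok], n_plain)
}

#' Generate disjoint chemical / plain word lists
#'
#' Chemical words are random syllable concatenations ending in a suffix from
#' the rule; plain words come from the packaged English list, filtered so no
#' plain word satisfies an entity suffix rule. Deterministic given the
#' spec's seed.
#'
#' @param spec A \code{\link{corpus_spec}}.
#' @return A \code{\link{build_word_lists}} result.
#' @export
generate_word_lists <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    plain <- plain_vocabulary(spec$n_plain)
    chem <- unique(random_words(spec$n_chemical * 2L, spec$suffixes))
    chem <- setdiff(chem, plain)
    chem <- utils::head(chem, spec$n_chemical)
    build_word_lists(chem, plain)
  })
}

class_vocabularies <- function(spec, plain) {
  vocabs <- list()
  for (cls in names(CLASS_SUFFIXES)) {
    suf <- if (cls == "CM") spec$suffixes else CLASS_SUFFIXES[[cls]]
    k <- if (cls == "CM") spec$n_chemical else max(spec$n_chemical %/% 4L,
                                                   10L)
    w <- unique(random_words(k * 2L, suf))
    vocabs[[cls]] <- utils::head(setdiff(w, plain), k)
  }
  # modifier words head multi-token entities ("ethyl"-style), so entity-
  # internal tokens are distinguishable from adjacent single-token entities
  w <- unique(random_words(spec$n_chemical, "yl"))
  vocabs$MOD <- utils::head(setdiff(w, plain), spec$n_chemical %/% 2L)
  vocabs
}

#' Generate a synthetic annotated corpus
#'
#' Builds sentences of plain words with entity tokens inserted at the spec's
#' rate; each entity's class is drawn from the class mix and realised as a
#' word carrying that class's suffix (two such words for multi-token
#' entities). Gold spans are recorded at insertion time — never by pattern
#' matching the rendered text — and each sentence is returned as an
#' \code{\link{annotated_document}}, whose construction re-tokenises the
#' text and verifies gold spans align with token boundaries. Fully
#' deterministic under the spec's seed.
#'
#' @param spec A \code{\link{corpus_spec}}.
#' @return List of \code{\link{annotated_document}} objects.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed + 1L, {
    plain <- plain_vocabulary(spec$n_plain)
    vocabs <- class_vocabularies(spec, plain)
    docs <- vector("list", spec$n_sentences)
    for (s in seq_len(spec$n_sentences)) {
      n_slots <- sample(5:12, 1)
      words <- character()
      entities <- list()
      pos <- 0L
      for (k in seq_len(n_slots)) {
        if (stats::runif(1) < spec$entity_rate) {
          cls <- sample(names(spec$class_mix), 1, prob = spec$class_mix)
          ew <- if (stats::runif(1) < spec$multi_rate)
            c(sample(vocabs$MOD, 1), sample(vocabs[[cls]], 1))
          else sample(vocabs[[cls]], 1)
          surface <- paste(ew, collapse = " ")
          entities[[length(entities) + 1L]] <-
            named_entity(surface, cls, pos, pos + nchar(surface))
          words <- c(words, ew)
          pos <- pos + nchar(surface) + 1L
        } else {
          w <- sample(plain, 1)
          words <- c(words, w)
          pos <- pos + nchar(w) + 1L
        }
      }
      text <- paste0(paste(words, collapse = " "), ".")
      docs[[s]] <- annotated_document(text, entities)
    }
    docs
  })
}

#' Write a generated corpus to disk
#'
#' One plain-text file and one standoff JSON file per document, plus the
#' word lists; the layout consumed by the command-line \code{train-memm}
#' subcommand.
#'
#' @param spec A \code{\link{corpus_spec}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_corpus <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  docs <- generate_corpus(spec)
  for (i in seq_along(docs)) {
    base <- file.path(dir, sprintf("doc%04d", i))
    writeLines(docs[[i]]$text, paste0(base, ".txt"), useBytes = TRUE)
    write_standoff(docs[[i]]$entities, paste0(base, ".json"))
  }
  lists <- generate_word_lists(spec)
  writeLines(lists$chemical, file.path(dir, "chemical_words.txt"))
  writeLines(lists$nonchemical, file.path(dir, "plain_words.txt"))
  invisible(dir)
}

#' Read a corpus directory written by \code{\link{write_corpus}}
#'
#' @param dir Corpus directory.
#' @return List of \code{\link{annotated_document}} objects.
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  txts <- txts[!basename(txts) %in% c("chemical_words.txt",
                                      "plain_words.txt")]
  lapply(txts, function(tf) {
    jf <- sub("\\.txt$", ".json", tf)
    text <- paste(readLines(tf, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    annotated_document(text, read_standoff(jf))
  })
}
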