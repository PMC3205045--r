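#' Regex recogniser configuration
#'
#' Finds whole tokens matching a regular expression; intended for compound
#' serial numbers such as "NSC-2648".
#'
#' @param pattern Regular expression (anchored matching is the caller's
#'   responsibility; the default is fully anchored).
#' @param type Entity type to assign (default CM).
#' @return An object of class \code{"regex_config"}.
#' @export
regex_config <- function(pattern = "^[A-Z]{2,4}-[0-9]+$", type = "CM") {
  ok <- tryCatch({
    suppressWarnings(grepl(pattern, "x", perl = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("invalid regular expression: ", pattern)
  type <- match.arg(type, ENTITY_TYPES)
  structure(list(pattern = pattern, type = type), class = "regex_config")
}

#' Find entities by whole-token regex match
#'
#' @param seq A \code{\link{token_sequence}}.
#' @param config A \code{\link{regex_config}}.
#' @return List of \code{\link{named_entity}} objects (confidence 1).
#' @export
regex_find <- function(seq, config = regex_config()) {
  out <- list()
  for (tok in seq$tokens) {
    if (grepl(config$pattern, tok$surface, perl = TRUE)) {
      out[[length(out) + 1L]] <-
        named_entity(tok$surface, config$type, tok$start, tok$end, 1.0)
    }
  }
  out
}

normalise_term <- function(x) {
  gsub("\\s+", " ", trimws(tolower(x)))
}

#' Build an ontology term table
#'
#' A multimap from normalised (case-folded, single-spaced) term to ontology
#' identifiers. Multi-word terms match across token boundaries.
#'
#' @param terms Character vector of terms.
#' @param ids Character vector (same length) of identifiers; repeated terms
#'   accumulate identifiers.
#' @return An object of class \code{"ontology_terms"}.
#' @export
ontology_terms <- function(terms, ids) {
  stopifnot(length(terms) == length(ids), length(terms) > 0,
            all(nzchar(terms)), all(nzchar(ids)))
  terms <- normalise_term(terms)
  tab <- split(as.character(ids), terms)
  tab <- lapply(tab, unique)
  structure(list(table = tab,
                 max_words = max(lengths(strsplit(names(tab), " ",
                                                  fixed = TRUE)))),
            class = "ontology_terms")
}

#' Read ontology terms from a TSV file
#'
#' Format: \code{term<TAB>id}, one line per (term, id) pair; repeated term
#' lines accumulate identifiers. No header.
#'
#' @param path Path to the TSV file.
#' @return An \code{"ontology_terms"} object.
#' @export
read_ontology_terms <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8",
                          col.names = c("term", "id"))
  ontology_terms(df$term, df$id)
}

#' Find ontology terms by longest-leftmost dictionary lookup
#'
#' Scans token positions left to right; at each position the longest
#' token-aligned term match wins and the scan resumes after it. Matching is
#' on normalised token surfaces joined by single spaces. Matched entities
#' carry every identifier registered for the term.
#'
#' @param seq A \code{\link{token_sequence}}.
#' @param terms An \code{\link{ontology_terms}} table.
#' @return List of ONT \code{\link{named_entity}} objects.
#' @export
ontology_find <- function(seq, terms) {
  stopifnot(inherits(terms, "ontology_terms"))
  toks <- seq$tokens
  n <- length(toks)
  if (!n) return(list())
  norm <- normalise_term(token_surfaces(seq))
  out <- list()
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (k in seq(min(terms$max_words, n - i + 1L), 1L)) {
      key <- paste(norm[i:(i + k - 1L)], collapse = " ")
      if (!is.null(terms$table[[key]])) { hit <- k; break }
    }
    if (hit > 0L) {
      j <- i + hit - 1L
      key <- paste(norm[i:j], collapse = " ")
      out[[length(out) + 1L]] <- named_entity(
        slice_text(seq$text, toks[[i]]$start - seq$offset,
                   toks[[j]]$end - seq$offset),
        "ONT", toks[[i]]$start, toks[[j]]$end, 1.0,
        ontology_ids = terms$table[[key]])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

GREEK_NAMES <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                 "eta", "theta", "iota", "kappa", "lambda", "mu", "nu",
                 "xi", "omicron", "pi", "rho", "sigma", "tau", "upsilon",
                 "phi", "chi", "psi", "omega")
GREEK_SYMBOLS <- strsplit("αβγδεζηθικλμνξοπρστυφχψω", "")[[1]]

DEFAULT_PREFIX_ITEMS <- c(GREEK_NAMES, GREEK_SYMBOLS,
                          "R", "S", "E", "Z", "cis", "trans",
                          "o", "m", "p", "N", "O", "sec", "tert", "n")

#' Build the chemical locant-prefix automaton
#'
#' A deterministic finite automaton accepting locant prefixes at token start:
#' one or more items — digit runs, Greek letter names or symbols, R/S/E/Z
#' stereo-descriptors, cis/trans, o/m/p, N/O locants — separated by commas
#' and terminated by a hyphen. It accepts only strings ending in "-" and
#' rejects the empty string. The item vocabulary is data, so users can
#' extend it.
#'
#' @param items Literal item strings (besides digit runs).
#' @param digits Allow digit-run items (default TRUE).
#' @return An object of class \code{"prefix_automaton"}: explicit transition
#'   tables plus the accepting-state set.
#' @export
prefix_automaton <- function(items = DEFAULT_PREFIX_ITEMS, digits = TRUE) {
  stopifnot(length(items) > 0 || digits)
  # state 1: item start; state 2: digit run (item complete); state 3: accept
  # (just consumed "-"); trie states for literal items follow.
  trans <- list()          # per state: named integer vector char -> state
  item_done <- logical()   # states where an item has just been completed
  new_state <- function() {
    trans[[length(trans) + 1L]] <<- integer()
    item_done[length(trans)] <<- FALSE
    length(trans)
  }
  START <- new_state(); DIGIT <- new_state(); ACCEPT <- new_state()
  if (digits) {
    for (d in as.character(0:9)) {
      trans[[START]][d] <- DIGIT
      trans[[DIGIT]][d] <- DIGIT
    }
    item_done[DIGIT] <- TRUE
  }
  for (it in items) {
    st <- START
    for (ch in strsplit(it, "")[[1]]) {
      nxt <- trans[[st]][ch]
      if (is.na(nxt) || nxt == DIGIT || nxt == ACCEPT) {
        nxt <- new_state()
        trans[[st]][ch] <- nxt
      }
      st <- nxt
    }
    item_done[st] <- TRUE
  }
  for (st in which(item_done)) {
    trans[[st]][","] <- START
    trans[[st]]["-"] <- ACCEPT
  }
  structure(list(transitions = trans, start = START, accept = ACCEPT,
                 items = items, digits = digits),
            class = "prefix_automaton")
}

#' Read a prefix grammar from a JSON file
#'
#' The file holds an object with keys \code{items} (literal strings) and
#' \code{digits} (logical).
#'
#' @param path Path to a JSON file.
#' @return A \code{\link{prefix_automaton}}.
#' @export
read_prefix_grammar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prefix_automaton(items = obj$items %||% DEFAULT_PREFIX_ITEMS,
                   digits = obj$digits %||% TRUE)
}

# Length of the longest accepting prefix of s, or 0.
prefix_longest_accept <- function(automaton, s) {
  st <- automaton$start
  best <- 0L
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    nxt <- automaton$transitions[[st]][chars[i]]
    if (is.na(nxt)) break
    st <- nxt
    if (st == automaton$accept) {
      best <- i
      break   # accept state is terminal: prefix ends at its hyphen
    }
  }
  best
}

#' Find chemical locant prefixes
#'
#' For each token, the longest accepting prefix of its surface (per the
#' automaton) becomes a CPR entity covering exactly those characters. Every
#' emitted span ends in "-".
#'
#' @param seq A \code{\link{token_sequence}}.
#' @param automaton A \code{\link{prefix_automaton}}.
#' @return List of CPR \code{\link{named_entity}} objects.
#' @export
prefix_find <- function(seq, automaton = prefix_automaton()) {
  out <- list()
  for (tok in seq$tokens) {
    len <- prefix_longest_accept(automaton, tok$surface)
    if (len > 0L) {
      out[[length(out) + 1L]] <-
        named_entity(substr(tok$surface, 1, len), "CPR", tok$start,
                     tok$start + len, 1.0)
    }
  }
  out
}
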