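DEFAULT_SPLIT_SUFFIXES <- c("based", "containing", "free", "rich",
                            "dependent", "induced", "mediated", "derived",
                            "treated")

DEFAULT_STRIP_CHARS <- c(".", ",", ";", ":", "!", "?", "\"", "'",
                         "(", ")", "[", "]", "{", "}")

DEFAULT_ABBREVIATIONS <- c("Anal.", "Calcd.", "calcd.", "Found.", "Fig.",
                           "Figs.", "cf.", "ca.", "eq.", "equiv.", "approx.",
                           "e.g.", "i.e.", "al.", "Ref.", "no.", "No.",
                           "mp.", "bp.")

#' Tokeniser configuration
#'
#' Controls the chemistry-aware tokeniser. \code{split_suffixes} are
#' lower-case hyphen suffixes that force an internal split ("water-based"
#' becomes "water", "-", "based"); hyphens not followed by one of them are
#' preserved, so "C-H" and "NSC-2648" stay single tokens.
#' \code{strip_punctuation} is the set of characters iteratively stripped off
#' token edges into separate tokens, with two exceptions: a trailing period
#' stays attached when the unit is a known abbreviation or a single letter
#' plus period, and an edge bracket stays attached when detaching it would
#' leave the bracket pair unbalanced inside the remaining token (so
#' "poly(ethylene)" survives intact while "(42)" splits).
#'
#' @param split_suffixes Character vector of lower-case suffixes.
#' @param strip_punctuation Character vector of single characters.
#' @param abbreviations Units (including their trailing period) whose period
#'   is never stripped.
#' @return An object of class \code{"tokeniser_config"}.
#' @export
tokeniser_config <- function(split_suffixes = DEFAULT_SPLIT_SUFFIXES,
                             strip_punctuation = DEFAULT_STRIP_CHARS,
                             abbreviations = DEFAULT_ABBREVIATIONS) {
  stopifnot(length(strip_punctuation) > 0,
            all(nchar(strip_punctuation) == 1L),
            identical(split_suffixes, tolower(split_suffixes)))
  structure(list(split_suffixes = split_suffixes,
                 strip_punctuation = strip_punctuation,
                 abbreviations = abbreviations),
            class = "tokeniser_config")
}

#' Load a tokeniser configuration from a JSON file
#'
#' The file may override any of \code{split_suffixes},
#' \code{strip_punctuation} and \code{abbreviations}; omitted keys keep their
#' defaults.
#'
#' @param path Path to a JSON object file.
#' @return A \code{\link{tokeniser_config}}.
#' @export
read_tokeniser_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tokeniser_config(
    split_suffixes = cfg$split_suffixes %||% DEFAULT_SPLIT_SUFFIXES,
    strip_punctuation = cfg$strip_punctuation %||% DEFAULT_STRIP_CHARS,
    abbreviations = cfg$abbreviations %||% DEFAULT_ABBREVIATIONS)
}

#' NFC-normalise document text
#'
#' All offsets produced by the toolkit index into the NFC-normalised text;
#' normalise once before any processing.
#'
#' @param text Character scalar.
#' @return NFC-normalised text.
#' @export
normalize_text <- function(text) {
  stringi::stri_trans_nfc(text)
}

# Subscript digits mapped to ASCII for classifier-facing surfaces; offsets
# always refer to the unmapped text.
normalize_surface <- function(x) {
  chartr("₀₁₂₃₄₅₆₇₈₉",
         "0123456789", x)
}

#' Split a document into paragraph skeletons
#'
#' Paragraphs are maximal runs of text separated by one or more blank lines.
#' Each skeleton records the paragraph text and the document offset (0-based
#' code points) of its first character, so concatenating paragraphs and
#' separators reconstructs the input.
#'
#' @param text Document text (NFC-normalised).
#' @return List of \code{list(text=, offset=)} skeletons.
#' @export
split_paragraphs <- function(text) {
  if (!nzchar(text)) return(list())
  seps <- stringi::stri_locate_all_regex(text, "\\n([ \\t]*\\n)+")[[1]]
  bounds <- c(0L)
  if (!is.na(seps[1, 1])) {
    for (i in seq_len(nrow(seps))) {
      bounds <- c(bounds, seps[i, 1] - 1L, seps[i, 2])
    }
  }
  bounds <- c(bounds, stringi::stri_length(text))
  out <- list()
  for (i in seq(1, length(bounds), by = 2)) {
    s <- bounds[i]; e <- bounds[i + 1]
    if (e > s) {
      chunk <- slice_text(text, s, e)
      if (nzchar(trimws(chunk)))
        out[[length(out) + 1L]] <- list(text = chunk, offset = as.integer(s))
    }
  }
  out
}

BRACKET_CLOSE <- c("(" = ")", "[" = "]", "{" = "}")
BRACKET_OPEN <- c(")" = "(", "]" = "[", "}" = "{")

balanced_pair <- function(s, open, close) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  sum(ch == open) == sum(ch == close)
}

# May an edge bracket be detached? Yes when the remainder is balanced for
# that pair, or when the bracket belongs to a pair wrapping the whole unit.
bracket_strip_ok <- function(u, side) {
  n <- nchar(u)
  c0 <- if (side == "left") substr(u, 1, 1) else substr(u, n, n)
  if (!c0 %in% c(names(BRACKET_CLOSE), names(BRACKET_OPEN))) return(TRUE)
  r <- if (side == "left") substr(u, 2, n) else substr(u, 1, n - 1)
  open <- if (c0 %in% names(BRACKET_CLOSE)) c0 else BRACKET_OPEN[[c0]]
  close <- BRACKET_CLOSE[[open]]
  if (balanced_pair(r, open, close)) return(TRUE)
  if (side == "left" && c0 == open && substr(u, n, n) == close &&
      balanced_pair(substr(u, 2, n - 1), open, close)) return(TRUE)
  if (side == "right" && c0 == close && substr(u, 1, 1) == open &&
      balanced_pair(substr(u, 2, n - 1), open, close)) return(TRUE)
  FALSE
}

keep_trailing_period <- function(u, config) {
  u %in% config$abbreviations ||
    (nchar(u) == 2L && grepl("^[A-Za-z]\\.$", u))
}

# Tokenise one whitespace-delimited unit starting at document offset s
# (0-based). Returns list of (surface, start) pairs.
tokenise_unit <- function(u, s, config) {
  pre <- list(); post <- list()
  e <- s + nchar(u)
  repeat {
    n <- nchar(u)
    if (n <= 1L) break
    first <- substr(u, 1, 1)
    if (first %in% config$strip_punctuation && bracket_strip_ok(u, "left")) {
      pre[[length(pre) + 1L]] <- list(surface = first, start = s)
      u <- substr(u, 2, n); s <- s + 1L
      next
    }
    last <- substr(u, n, n)
    if (last %in% config$strip_punctuation &&
        bracket_strip_ok(u, "right") &&
        !(last == "." && keep_trailing_period(u, config))) {
      post <- c(list(list(surface = last, start = e - 1L)), post)
      u <- substr(u, 1, n - 1); e <- e - 1L
      next
    }
    break
  }
  core <- list(list(surface = u, start = s))
  hy <- stringi::stri_locate_last_fixed(u, "-")[1, 1]
  if (!is.na(hy) && hy > 1 && hy < nchar(u)) {
    suffix <- substr(u, hy + 1, nchar(u))
    if (tolower(suffix) %in% config$split_suffixes) {
      core <- list(list(surface = substr(u, 1, hy - 1), start = s),
                   list(surface = "-", start = s + hy - 1L),
                   list(surface = suffix, start = s + hy))
    }
  }
  c(pre, core, post)
}

#' Tokenise a paragraph
#'
#' Splits on whitespace, then iteratively detaches edge punctuation into
#' separate tokens under the rules documented in
#' \code{\link{tokeniser_config}}. Every token satisfies offset fidelity:
#' slicing the document by \code{[start, end)} reproduces its surface.
#'
#' @param paragraph Paragraph text (non-empty after trimming).
#' @param offset Document offset of the paragraph's first character.
#' @param config A \code{\link{tokeniser_config}}.
#' @return A \code{\link{token_sequence}} with document-level offsets.
#' @export
tokenise <- function(paragraph, offset = 0L, config = tokeniser_config()) {
  stopifnot(nzchar(trimws(paragraph)), offset >= 0)
  locs <- stringi::stri_locate_all_regex(paragraph, "\\S+")[[1]]
  toks <- list()
  for (i in seq_len(nrow(locs))) {
    u <- substr(paragraph, locs[i, 1], locs[i, 2])
    s <- offset + locs[i, 1] - 1L
    for (p in tokenise_unit(u, s, config)) {
      toks[[length(toks) + 1L]] <-
        token(p$surface, p$start, p$start + nchar(p$surface))
    }
  }
  token_sequence(paragraph, offset, toks)
}

#' Tokenise a whole document
#'
#' NFC-normalises, splits into paragraphs and tokenises each.
#'
#' @param text Document text.
#' @param config A \code{\link{tokeniser_config}}.
#' @return List of \code{\link{token_sequence}} objects.
#' @export
tokenise_document <- function(text, config = tokeniser_config()) {
  text <- normalize_text(text)
  lapply(split_paragraphs(text), function(p)
    tokenise(p$text, p$offset, config))
}
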