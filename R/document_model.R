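#' @importFrom stats optim setNames
#' @importFrom utils head tail read.csv
NULL

# Entity classes: chemical, ontology term, reaction, chemical adjective,
# enzyme, chemical prefix; DATA is reserved for experimental-data annotations
# so they can share the standoff channel.
ENTITY_TYPES <- c("CM", "ONT", "RN", "CJ", "ASE", "CPR", "DATA")

#' Entity types recognised by the toolkit
#'
#' Returns the closed set of entity type codes: \code{CM} (chemical),
#' \code{ONT} (ontology term), \code{RN} (reaction), \code{CJ} (chemical
#' adjective), \code{ASE} (enzyme), \code{CPR} (chemical prefix) and
#' \code{DATA} (experimental-data annotation).
#'
#' @return Character vector of type codes.
#' @export
entity_types <- function() ENTITY_TYPES

#' Construct a token
#'
#' A token is a positioned unit of text: its surface string plus 0-based,
#' half-open character offsets into the source document. Offsets are
#' code-point offsets into the NFC-normalised document text, so
#' \code{substr(text, start + 1, end)} always reproduces \code{surface}.
#'
#' @param surface Non-empty token string.
#' @param start,end 0-based half-open character offsets (\code{end > start}).
#' @param index Position of the token within its sequence (1-based).
#' @return An object of class \code{"chem_token"}.
#' @export
token <- function(surface, start, end, index = NA_integer_) {
  stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface),
            end > start, start >= 0)
  structure(list(surface = surface, start = as.integer(start),
                 end = as.integer(end), index = as.integer(index)),
            class = "chem_token")
}

#' Construct a token sequence
#'
#' A token sequence holds one paragraph of text, the document offset of its
#' first character, and its ordered, non-overlapping tokens. All token
#' offsets are document-level.
#'
#' @param text Paragraph text.
#' @param offset Document offset (0-based) of the paragraph's first character.
#' @param tokens List of \code{\link{token}} objects, ordered by start.
#' @return An object of class \code{"chem_token_sequence"}.
#' @export
token_sequence <- function(text, offset, tokens) {
  offset <- as.integer(offset)
  if (length(tokens)) {
    starts <- vapply(tokens, `[[`, integer(1), "start")
    ends <- vapply(tokens, `[[`, integer(1), "end")
    if (is.unsorted(starts)) stop("tokens must be ordered by start")
    if (any(starts[-1] < ends[-length(ends)]))
      stop("tokens must not overlap")
    if (any(starts < offset) || any(ends > offset + nchar(text)))
      stop("tokens must lie within the paragraph")
    for (i in seq_along(tokens)) tokens[[i]]$index <- i
  }
  structure(list(text = text, offset = offset, tokens = tokens),
            class = "chem_token_sequence")
}

#' @export
print.chem_token_sequence <- function(x, ...) {
  cat(sprintf("<token sequence: %d tokens, offset %d>\n",
              length(x$tokens), x$offset))
  if (length(x$tokens))
    cat(" ", paste(vapply(x$tokens, `[[`, character(1), "surface"),
                   collapse = " | "), "\n")
  invisible(x)
}

token_surfaces <- function(seq) {
  vapply(seq$tokens, `[[`, character(1), "surface")
}

#' Construct a named entity
#'
#' An offset-anchored, typed text span. \code{start}/\code{end} are 0-based
#' half-open document character offsets; \code{confidence}, when present,
#' lies in \eqn{[0,1]}; \code{ontology_ids} carries ontology identifiers for
#' ONT entities.
#'
#' @param surface Entity surface string.
#' @param type One of \code{entity_types()}.
#' @param start,end Document character offsets.
#' @param confidence Numeric in \eqn{[0,1]} or \code{NA}.
#' @param ontology_ids Character vector of ontology identifiers.
#' @return An object of class \code{"chem_named_entity"}.
#' @export
named_entity <- function(surface, type, start, end, confidence = NA_real_,
                         ontology_ids = character()) {
  type <- match.arg(type, ENTITY_TYPES)
  stopifnot(end > start, start >= 0)
  if (!is.na(confidence) && (confidence < 0 || confidence > 1))
    stop("confidence must lie in [0,1]")
  structure(list(surface = surface, type = type, start = as.integer(start),
                 end = as.integer(end), confidence = as.numeric(confidence),
                 ontology_ids = as.character(ontology_ids)),
            class = "chem_named_entity")
}

#' @export
print.chem_named_entity <- function(x, ...) {
  conf <- if (is.na(x$confidence)) "" else sprintf(" conf=%.3f", x$confidence)
  ids <- if (length(x$ontology_ids))
    paste0(" ids=[", paste(x$ontology_ids, collapse = ","), "]") else ""
  cat(sprintf("<%s [%d,%d) \"%s\"%s%s>\n", x$type, x$start, x$end,
              x$surface, conf, ids))
  invisible(x)
}

STRUCTURE_FORMATS <- c("SMILES", "INCHI", "CML")

#' Construct a chemical structure record
#'
#' @param format One of \code{"SMILES"}, \code{"INCHI"}, \code{"CML"}.
#' @param value Non-empty structure string.
#' @return An object of class \code{"chem_structure"}.
#' @export
chemical_structure <- function(format, value) {
  format <- match.arg(toupper(format), STRUCTURE_FORMATS)
  stopifnot(is.character(value), length(value) == 1L, nzchar(value))
  structure(list(format = format, value = value), class = "chem_structure")
}

#' Construct a resolved named entity
#'
#' Links a named entity to a non-empty ordered list of chemical structures.
#' Unresolvable entities are represented by absence, never by an empty
#' structure list.
#'
#' @param entity A \code{\link{named_entity}}.
#' @param structures Non-empty list of \code{\link{chemical_structure}}s.
#' @return An object of class \code{"chem_resolved_entity"}.
#' @export
resolved_named_entity <- function(entity, structures) {
  if (!length(structures))
    stop("a resolved entity must carry at least one structure")
  structure(list(entity = entity, structures = structures),
            class = "chem_resolved_entity")
}

#' @export
print.chem_resolved_entity <- function(x, ...) {
  cat(sprintf("<resolved %s \"%s\": %d structure(s)>\n", x$entity$type,
              x$entity$surface, length(x$structures)))
  for (s in x$structures) cat(sprintf("  %s: %s\n", s$format, s$value))
  invisible(x)
}

#' Do two entity spans overlap?
#'
#' Half-open interval intersection: spans \code{[a_start, a_end)} and
#' \code{[b_start, b_end)} overlap iff
#' \code{max(starts) < min(ends)}; adjacent spans do not overlap.
#'
#' @param a,b \code{\link{named_entity}} objects anchored to one document.
#' @return Logical.
#' @export
entities_overlap <- function(a, b) {
  max(a$start, b$start) < min(a$end, b$end)
}

#' Serialise entities to standoff records
#'
#' Converts a list of named entities into a standoff data frame (one row per
#' entity: type, start, end, surface, confidence, ids) preserving order. The
#' data frame round-trips losslessly through \code{\link{write_standoff}} /
#' \code{\link{read_standoff}}.
#'
#' @param entities List of \code{\link{named_entity}} objects.
#' @return A data frame with columns \code{type}, \code{start}, \code{end},
#'   \code{surface}, \code{confidence}, \code{ids} (list column).
#' @export
to_standoff <- function(entities) {
  data.frame(
    type = vapply(entities, `[[`, character(1), "type"),
    start = vapply(entities, `[[`, integer(1), "start"),
    end = vapply(entities, `[[`, integer(1), "end"),
    surface = vapply(entities, `[[`, character(1), "surface"),
    confidence = vapply(entities, `[[`, numeric(1), "confidence"),
    ids = I(lapply(entities, `[[`, "ontology_ids")),
    stringsAsFactors = FALSE
  )
}

#' Rebuild entities from standoff records
#'
#' Inverse of \code{\link{to_standoff}}.
#'
#' @param records Data frame as produced by \code{\link{to_standoff}}.
#' @return List of \code{\link{named_entity}} objects.
#' @export
from_standoff <- function(records) {
  lapply(seq_len(nrow(records)), function(i) {
    ids <- records$ids[[i]]
    named_entity(records$surface[i], records$type[i], records$start[i],
                 records$end[i], records$confidence[i],
                 if (is.null(ids)) character() else ids)
  })
}

#' Write standoff annotations to JSON or TSV
#'
#' The JSON dialect is a list of objects with keys \code{type}, \code{start},
#' \code{end}, \code{surface}, \code{confidence}, \code{ids}; the TSV variant
#' has the same columns (ids comma-joined), one entity per line with a header
#' row.
#'
#' @param entities List of \code{\link{named_entity}} objects.
#' @param path Output file path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @export
write_standoff <- function(entities, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  rec <- to_standoff(entities)
  if (format == "json") {
    objs <- lapply(seq_len(nrow(rec)), function(i) {
      list(type = rec$type[i], start = rec$start[i], end = rec$end[i],
           surface = rec$surface[i],
           confidence = if (is.na(rec$confidence[i])) NULL else rec$confidence[i],
           ids = as.list(rec$ids[[i]]))
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    flat <- rec
    flat$ids <- vapply(rec$ids, paste, character(1), collapse = ",")
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read standoff annotations written by \code{\link{write_standoff}}
#'
#' @param path Input file path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return List of \code{\link{named_entity}} objects.
#' @export
read_standoff <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    objs <- jsonlite::read_json(path)
    lapply(objs, function(o) {
      named_entity(o$surface, o$type, o$start, o$end,
                   if (is.null(o$confidence)) NA_real_ else o$confidence,
                   unlist(o$ids) %||% character())
    })
  } else {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8", quote = "")
    lapply(seq_len(nrow(df)), function(i) {
      ids <- if (is.na(df$ids[i]) || !nzchar(df$ids[i])) character()
             else strsplit(df$ids[i], ",", fixed = TRUE)[[1]]
      named_entity(df$surface[i], df$type[i], df$start[i], df$end[i],
                   df$confidence[i], ids)
    })
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open slice of document text by code points.
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}
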